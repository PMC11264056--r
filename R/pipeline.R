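# End-to-end orchestration: synthetic or EDF-directory input -> band MI
# feature table -> group statistics -> staging experiment, with every
# resolved default echoed into the run directory.

#' Pipeline configuration
#'
#' Builds the fully-resolved configuration for [run_pipeline()]. Every
#' methodological default left open by convention — histogram bin count,
#' filter order, post-hoc method, split unit, averaging scheme — is
#' materialized here so the run directory records it.
#'
#' @param mode `"synthetic"` (generate a cohort) or `"edf_dir"` (read
#'   `*-PSG.edf` / `*-Hypnogram.edf` pairs plus a `metadata.csv` with
#'   `subject_id`, `age`, `sex` from `input_dir`).
#' @param input_dir directory of EDF pairs (edf_dir mode).
#' @param seed root seed; all module streams derive from it.
#' @param cohort named list overriding [cohort_spec()] fields.
#' @param coupling named list overriding [coupling_table()] arguments.
#' @param bands named list of band overrides for [band_scheme()].
#' @param mi named list: `n_bins`, `aggregate`, `correction`.
#' @param stats named list: `alpha`, `posthoc_method`.
#' @param experiment named list: `classifiers`, `n_rounds`, `split`.
#' @param wake_trim_minutes optional wake trimming for edf_dir mode.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "edf_dir"), input_dir = NULL,
                            seed = 1, cohort = list(), coupling = list(),
                            bands = NULL, mi = list(), stats = list(),
                            experiment = list(), wake_trim_minutes = NULL) {
  mode <- match.arg(mode)
  merge_defaults <- function(defaults, user) {
    stopifnot(all(names(user) %in% names(defaults)))
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    mode = mode, input_dir = input_dir, seed = seed,
    cohort = merge_defaults(list(n_subjects = 2, epochs_per_stage = 5,
                                 noise_sd = 0), cohort),
    coupling = merge_defaults(list(sex_shift = 0.10, age_shift = 0.10), coupling),
    bands = bands,
    mi = merge_defaults(list(n_bins = 32, aggregate = "epoch",
                             correction = "none"), mi),
    stats = merge_defaults(list(alpha = 0.05, posthoc_method = "bonferroni"),
                           stats),
    experiment = merge_defaults(list(classifiers = CLASSIFIER_KINDS,
                                     n_rounds = 10, split = 0.7), experiment),
    wake_trim_minutes = wake_trim_minutes,
    filter = list(order = 4, zero_phase = TRUE, pad = 300),
    split_unit = "epoch")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

load_edf_dir <- function(input_dir, wake_trim_minutes = NULL) {
  meta_path <- file.path(input_dir, "metadata.csv")
  if (!file.exists(meta_path))
    stop("edf_dir mode needs ", meta_path, " with subject_id, age, sex")
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  psg <- sort(list.files(input_dir, pattern = "-PSG\\.edf$", full.names = TRUE))
  if (!length(psg)) stop("no *-PSG.edf files in ", input_dir)
  epochs <- list()
  for (p in psg) {
    sid <- sub("-PSG\\.edf$", "", basename(p))
    hyp <- file.path(input_dir, paste0(sid, "-Hypnogram.edf"))
    if (!file.exists(hyp)) stop("missing hypnogram for ", sid)
    row <- meta[meta$subject_id == sid, ]
    if (nrow(row) != 1) stop("no metadata row for ", sid)
    rec <- read_recording(p, subject_id = sid)
    eps <- segment_epochs(rec, read_hypnogram(hyp),
                          subject_meta(row$age, row$sex),
                          wake_trim_minutes = wake_trim_minutes)
    epochs <- c(epochs, eps)
  }
  epochs
}

#' Run the full analysis pipeline
#'
#' Synthetic mode generates a cohort; edf_dir mode reads EDF pairs. Either
#' way the pipeline computes the per-epoch six-band MI feature table, the
#' stage/age/sex group statistics, and the subgroup staging experiment, and
#' writes `features.csv`, `group_stats_omnibus.csv`,
#' `group_stats_pairwise.csv`, `group_stats.json`, `staging.csv`,
#' `staging_summary.csv` and `run_log.yaml` (config echo, row counts,
#' package version) into `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with `features`, `group_stats`, `staging` and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    message(line)
    log_lines <<- c(log_lines, line)
  }

  scheme <- band_scheme(config$bands)
  if (config$mode == "synthetic") {
    coup <- do.call(coupling_table, config$coupling)
    spec <- cohort_spec(n_subjects = config$cohort$n_subjects,
                        epochs_per_stage = config$cohort$epochs_per_stage,
                        noise_sd = config$cohort$noise_sd,
                        seed = child_seed(config$seed, 1))
    cohort <- generate_cohort(spec, coup)
    epochs <- cohort$epochs
    say("input", "synthetic cohort: %d epochs, %d subjects",
        nrow(cohort$manifest), length(unique(cohort$manifest$subject_id)))
  } else {
    epochs <- load_edf_dir(config$input_dir, config$wake_trim_minutes)
    say("input", "edf_dir %s: %d epochs", config$input_dir, length(epochs))
  }

  epochs <- lapply(epochs, broadband_filter)
  say("preprocess", "broadband 0.5-30 Hz filtered %d epochs", length(epochs))

  features <- connectivity_features(epochs, scheme,
                                    n_bins = config$mi$n_bins,
                                    aggregate = config$mi$aggregate,
                                    correction = config$mi$correction)
  write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
  say("connectivity", "feature table: %d rows x %d bands", nrow(features),
      length(mi_columns(features)))

  gs <- run_group_analysis(features, alpha = config$stats$alpha,
                           posthoc_method = config$stats$posthoc_method)
  write.csv(gs$omnibus, file.path(out_dir, "group_stats_omnibus.csv"),
            row.names = FALSE)
  if (!is.null(gs$pairwise))
    write.csv(gs$pairwise, file.path(out_dir, "group_stats_pairwise.csv"),
              row.names = FALSE)
  jsonlite::write_json(list(omnibus = gs$omnibus, pairwise = gs$pairwise,
                            alpha = gs$alpha, posthoc = gs$posthoc_method,
                            correction_scope = gs$correction_scope),
                       file.path(out_dir, "group_stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("group_stats", "%d omnibus ANOVAs, %d pairwise comparisons",
      nrow(gs$omnibus), if (is.null(gs$pairwise)) 0L else nrow(gs$pairwise))

  suite <- run_subgroup_suite(features,
                              classifiers = config$experiment$classifiers,
                              n_rounds = config$experiment$n_rounds,
                              split = config$experiment$split,
                              seed = child_seed(config$seed, 2))
  write.csv(suite$table, file.path(out_dir, "staging.csv"), row.names = FALSE)
  write.csv(suite$summary, file.path(out_dir, "staging_summary.csv"),
            row.names = FALSE)
  say("staging", "%d classifier x subgroup runs", nrow(suite$table))

  echo <- unclass(config)
  echo$package_version <- as.character(utils::packageVersion("somniconn"))
  echo$log <- log_lines
  yaml::write_yaml(echo, file.path(out_dir, "run_log.yaml"))
  invisible(list(features = features, group_stats = gs, staging = suite,
                 out_dir = out_dir))
}
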