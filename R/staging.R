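# Sleep-staging experiment: balanced downsampling, repeated stratified 7:3
# splits, three classifiers (SVM with RBF kernel, KNN with k = 9, random
# forest with 50 trees), and macro-averaged metrics over the five stages.

CLASSIFIER_KINDS <- c("rf", "svm", "knn")

#' Classifier specification
#'
#' Fixed operating points: k = 9 neighbours for KNN and 50 trees for the
#' random forest; the SVM uses a radial-basis-function kernel with library
#' default cost and gamma. Remaining settings are the implementation
#' defaults of \pkg{randomForest}, \pkg{e1071} and \pkg{class}, recorded in
#' the returned object.
#'
#' @param kind `"rf"`, `"svm"` or `"knn"`.
#' @param k_neighbors KNN neighbourhood size.
#' @param n_trees random-forest size.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(kind = CLASSIFIER_KINDS, k_neighbors = 9,
                            n_trees = 50) {
  kind <- match.arg(kind)
  structure(list(kind = kind, k_neighbors = k_neighbors, n_trees = n_trees,
                 svm_kernel = "radial",
                 defaults = "e1071::svm / class::knn / randomForest defaults"),
            class = "classifier_spec")
}

#' Balance stage counts by random downsampling
#'
#' Randomly removes epochs from the majority stages until every stage
#' matches the minority stage's count.
#'
#' @param features a feature table with a `stage` column.
#' @param seed integer seed making the retained set reproducible.
#' @return the balanced subset (row order preserved).
#' @export
downsample_balance <- function(features, seed = 1) {
  stopifnot(is.data.frame(features), "stage" %in% names(features))
  missing <- setdiff(STAGE_LEVELS, unique(features$stage))
  if (length(missing))
    stop("stage(s) absent from the data: ", paste(missing, collapse = ", "))
  counts <- table(features$stage)
  n_min <- min(counts)
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(features)), features$stage),
                  function(idx) if (length(idx) > n_min) sample(idx, n_min) else idx))
  })
  features[sort(keep), , drop = FALSE]
}

# Standardize test features with training-fold statistics; essential for
# the distance-based (KNN) and margin-based (SVM) classifiers.
zscore_by_train <- function(train, test) {
  mu <- colMeans(train)
  sg <- apply(train, 2, sd)
  sg[sg == 0] <- 1
  list(train = scale(train, center = mu, scale = sg),
       test = scale(test, center = mu, scale = sg))
}

fit_predict <- function(spec, x_train, y_train, x_test) {
  switch(spec$kind,
    rf = {
      fit <- randomForest::randomForest(x = x_train, y = y_train,
                                        ntree = spec$n_trees)
      predict(fit, x_test)
    },
    svm = {
      z <- zscore_by_train(x_train, x_test)
      fit <- e1071::svm(x = z$train, y = y_train, kernel = spec$svm_kernel,
                        scale = FALSE)
      predict(fit, z$test)
    },
    knn = {
      z <- zscore_by_train(x_train, x_test)
      class::knn(z$train, z$test, cl = y_train, k = spec$k_neighbors)
    })
}

#' Macro-averaged classification metrics from a confusion matrix
#'
#' Overall accuracy is the trace over the total. Precision, recall and F1
#' are computed per class one-vs-rest — `TP/(TP+FP)`, `TP/(TP+FN)` and
#' `2 TP/(2 TP+FP+FN)` — then macro-averaged with equal class weight. A
#' class with zero predicted positives contributes precision 0 (noted via
#' `message`), keeping the macro average finite.
#'
#' @param cm square confusion matrix of counts, rows = true class,
#'   columns = predicted class.
#' @return named numeric: `accuracy`, `precision`, `recall`, `f1`, all in
#'   percent.
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), sum(cm) > 0, all(cm >= 0))
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  if (any(tp + fp == 0))
    message("class(es) with zero predicted positives: precision set to 0")
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))
  c(accuracy = 100 * sum(tp) / total, precision = 100 * mean(prec),
    recall = 100 * mean(rec), f1 = 100 * mean(f1))
}

#' Repeated-split staging experiment for one classifier
#'
#' Each round: rebalance the stage counts by random downsampling (seeded
#' `seed + round`), split 70/30 stratified by stage, fit, predict the test
#' epochs, and score the 5 x 5 confusion matrix. Returns mean and standard
#' deviation over rounds of the four metrics (percent).
#'
#' @param features feature table with `stage` and `mi_*` columns.
#' @param spec a [classifier_spec()].
#' @param n_rounds number of repeated rounds.
#' @param split training fraction.
#' @param seed integer root seed.
#' @param permute_labels if `TRUE`, stage labels are randomly permuted each
#'   round — the chance-level baseline (20% for five balanced stages).
#' @return a `staging_result`: list with `mean`, `sd` (named metric
#'   vectors), `rounds` (per-round metric matrix), `confusion` (summed over
#'   rounds) and the settings.
#' @export
run_experiment <- function(features, spec = classifier_spec("rf"),
                           n_rounds = 10, split = 0.7, seed = 1,
                           permute_labels = FALSE) {
  stopifnot(inherits(spec, "classifier_spec"), split > 0, split < 1)
  feat_cols <- mi_columns(features)
  stopifnot(length(feat_cols) >= 1)
  rounds <- matrix(NA_real_, n_rounds, 4,
                   dimnames = list(NULL, c("accuracy", "precision", "recall", "f1")))
  confusion <- matrix(0, 5, 5, dimnames = list(true = STAGE_LEVELS,
                                               predicted = STAGE_LEVELS))
  for (r in seq_len(n_rounds)) {
    bal <- downsample_balance(features, seed = child_seed(seed, r))
    if (min(table(bal$stage)) < 10)
      stop("too few epochs to split: ", min(table(bal$stage)),
           " per stage after balancing (need >= 10)")
    with_seed(child_seed(seed, 1000L + r), {
      y <- factor(bal$stage, levels = STAGE_LEVELS)
      if (permute_labels) y <- sample(y)
      test_idx <- unlist(lapply(split(seq_len(nrow(bal)), y), function(idx)
        sample(idx, max(1, round((1 - split) * length(idx))))))
      x <- as.matrix(bal[, feat_cols, drop = FALSE])
      pred <- fit_predict(spec, x[-test_idx, , drop = FALSE], y[-test_idx],
                          x[test_idx, , drop = FALSE])
      cm <- table(factor(y[test_idx], levels = STAGE_LEVELS),
                  factor(pred, levels = STAGE_LEVELS))
      rounds[r, ] <- suppressMessages(compute_metrics(cm))
      confusion <- confusion + cm
    })
  }
  structure(list(mean = colMeans(rounds), sd = apply(rounds, 2, sd),
                 rounds = rounds, confusion = confusion, spec = spec,
                 n_rounds = n_rounds, split = split, seed = seed,
                 permuted = permute_labels),
            class = "staging_result")
}

#' @export
print.staging_result <- function(x, ...) {
  cat(sprintf("<staging_result> %s%s: %d rounds, %.0f/%.0f split\n",
              x$spec$kind, if (x$permuted) " (permuted labels)" else "",
              x$n_rounds, 100 * x$split, 100 * (1 - x$split)))
  for (m in names(x$mean))
    cat(sprintf("  %-9s %5.2f +/- %.2f %%\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' Staging experiment across subgroups
#'
#' Runs [run_experiment()] for every classifier on the full table (`all`)
#' and on each age-group x sex subgroup, then summarizes the subgroup mean
#' accuracy and its difference from the all-sample accuracy per classifier
#' (the "does finer grouping help?" statistic). Subgroups that are empty or
#' too small to split are skipped with a warning.
#'
#' @param features feature table with `stage`, `age_group`, `sex` and
#'   `mi_*` columns.
#' @param classifiers character vector over `"rf"`, `"svm"`, `"knn"`.
#' @param n_rounds,split,seed passed to [run_experiment()].
#' @return a `staging_suite`: list with `table` (one row per classifier x
#'   subgroup: mean/sd of each metric), `summary` (per classifier: all
#'   accuracy, subgroup mean accuracy, gain), and `results` (the raw
#'   `staging_result` objects).
#' @export
run_subgroup_suite <- function(features, classifiers = CLASSIFIER_KINDS,
                               n_rounds = 10, split = 0.7, seed = 1) {
  cells <- expand.grid(age_group = AGE_LEVELS, sex = SEX_LEVELS,
                       stringsAsFactors = FALSE)
  subgroups <- c(list(all = features),
                 setNames(lapply(seq_len(nrow(cells)), function(i)
                   features[features$age_group == cells$age_group[i] &
                            features$sex == cells$sex[i], , drop = FALSE]),
                   paste(cells$age_group, cells$sex, sep = "_")))
  rows <- list(); results <- list()
  for (cl in classifiers) {
    spec <- classifier_spec(cl)
    for (gname in names(subgroups)) {
      sub <- subgroups[[gname]]
      if (nrow(sub) == 0) {
        warning("empty subgroup skipped: ", gname)
        next
      }
      res <- tryCatch(run_experiment(sub, spec, n_rounds, split,
                                     seed = child_seed(seed, match(cl, CLASSIFIER_KINDS) * 100L +
                                                               match(gname, names(subgroups)))),
                      error = function(e) {
                        warning("subgroup ", gname, " skipped for ", cl, ": ",
                                conditionMessage(e))
                        NULL
                      })
      if (is.null(res)) next
      results[[paste(cl, gname, sep = ".")]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = cl, subgroup = gname, t(res$mean),
        accuracy_sd = res$sd["accuracy"], precision_sd = res$sd["precision"],
        recall_sd = res$sd["recall"], f1_sd = res$sd["f1"],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  summ <- do.call(rbind, lapply(unique(tab$classifier), function(cl) {
    sub <- tab[tab$classifier == cl, ]
    all_acc <- sub$accuracy[sub$subgroup == "all"]
    grp_acc <- mean(sub$accuracy[sub$subgroup != "all"])
    data.frame(classifier = cl, all_accuracy = all_acc,
               subgroup_mean_accuracy = grp_acc,
               subgroup_gain = grp_acc - all_acc, stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, summary = summ, results = results,
                 n_rounds = n_rounds, split = split, seed = seed),
            class = "staging_suite")
}

#' @export
print.staging_suite <- function(x, ...) {
  cat("<staging_suite>", nrow(x$table), "classifier x subgroup runs\n")
  tab <- x$table
  tab[, 3:10] <- round(tab[, 3:10], 2)
  print(tab[, c("classifier", "subgroup", "accuracy", "accuracy_sd",
                "precision", "recall", "f1")], row.names = FALSE)
  cat("\nSubgroup gain (subgroup mean accuracy - all-sample accuracy):\n")
  summ <- x$summary
  summ[, -1] <- round(summ[, -1], 2)
  print(summ, row.names = FALSE)
  invisible(x)
}
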