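# Group comparison of band-wise connectivity: one-way ANOVA per band and
# factor, gated post-hoc pairwise tests when the omnibus test is significant
# at 0.05, Bonferroni correction within each omnibus family.

#' Significance stars for a p value
#'
#' The conventional threshold map: `p < 0.001` three stars, `p < 0.01` two,
#' `p < 0.05` one, otherwise empty.
#'
#' @param p numeric vector of p values.
#' @return character vector of star codes.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' One-way ANOVA over a list of samples
#'
#' The classical between/within mean-square ratio with `(k - 1, N - k)`
#' degrees of freedom, fitted via `lm`.
#'
#' @param groups list of numeric vectors, each a group's values (>= 2 groups
#'   of >= 2 values; zero total variance is an error).
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop("every group needs >= 2 values (group ",
         which(sizes < 2)[1], " has ", min(sizes), ")")
  y <- unlist(groups, use.names = FALSE)
  if (var(y) == 0) stop("zero variance: all values identical")
  g <- factor(rep(seq_along(groups), sizes))
  tab <- anova(lm(y ~ g))
  F <- tab[["F value"]][1]
  list(F = F, p = tab[["Pr(>F)"]][1], df1 = tab$Df[1], df2 = tab$Df[2])
}

#' Gated post-hoc pairwise comparisons
#'
#' All `k(k-1)/2` pairwise two-sample tests, Bonferroni-adjusted (or Tukey
#' HSD), only admissible after a significant omnibus ANOVA — calling it
#' without one is an error, enforcing the gated procedure.
#'
#' @param groups list of numeric vectors.
#' @param labels group names (defaults to list names or indices).
#' @param omnibus_p the omnibus ANOVA p value; must be < `alpha`.
#' @param alpha gate level, 0.05.
#' @param method `"bonferroni"` (Welch pairwise t tests, the default) or
#'   `"tukey"` (Tukey HSD on the pooled fit).
#' @return data frame with `group_a`, `group_b`, `adjusted_p`, `stars`.
#' @export
pairwise_posthoc <- function(groups, labels = names(groups),
                             omnibus_p = one_way_anova(groups)$p,
                             alpha = 0.05, method = c("bonferroni", "tukey")) {
  method <- match.arg(method)
  if (is.null(labels)) labels <- as.character(seq_along(groups))
  if (!(omnibus_p < alpha))
    stop("post-hoc tests require a significant omnibus ANOVA (p = ",
         signif(omnibus_p, 3), " >= ", alpha, ")")
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  if (method == "bonferroni") {
    raw <- apply(pairs, 2, function(ij)
      t.test(groups[[ij[1]]], groups[[ij[2]]])$p.value)  # Welch by default
    adj <- pmin(raw * ncol(pairs), 1)
  } else {
    y <- unlist(groups, use.names = FALSE)
    g <- factor(rep(labels, lengths(groups)), levels = labels)
    tk <- stats::TukeyHSD(stats::aov(y ~ g))$g
    key <- paste(labels[pairs[2, ]], labels[pairs[1, ]], sep = "-")
    adj <- unname(tk[key, "p adj"])
  }
  data.frame(group_a = labels[pairs[1, ]], group_b = labels[pairs[2, ]],
             adjusted_p = adj, stars = p_stars(adj), stringsAsFactors = FALSE)
}

anova_one_factor <- function(features, band_col, factor_col, context,
                             alpha = 0.05, posthoc_method = "bonferroni") {
  f <- factor(features[[factor_col]])
  levs <- levels(droplevels(f))
  if (length(levs) < 2) return(NULL)
  groups <- split(features[[band_col]], droplevels(f))
  if (any(lengths(groups) < 2)) return(NULL)
  om <- tryCatch(one_way_anova(groups), error = function(e) NULL)
  if (is.null(om)) return(NULL)
  ph <- if (om$p < alpha)
    pairwise_posthoc(groups, labels = levs, omnibus_p = om$p,
                     alpha = alpha, method = posthoc_method)
  else NULL
  list(omnibus = data.frame(factor = factor_col, context = context,
                            band = sub("^mi_", "", band_col),
                            F = om$F, p = om$p, stars = p_stars(om$p),
                            stringsAsFactors = FALSE),
       pairwise = if (!is.null(ph))
         cbind(data.frame(factor = factor_col, context = context,
                          band = sub("^mi_", "", band_col),
                          stringsAsFactors = FALSE), ph))
}

#' Full group analysis of a connectivity feature table
#'
#' Mirrors the three standard comparisons: per band, (i) connectivity
#' across the five sleep stages over all epochs; and within each stage,
#' (ii) across the three age groups and (iii) between the sexes. Each
#' omnibus ANOVA significant at `alpha` is followed by Bonferroni-adjusted
#' Welch pairwise tests (correction applied within that omnibus family
#' only). Comparisons with a missing factor level are skipped with a
#' warning.
#'
#' @param features a [connectivity_features()] table.
#' @param alpha omnibus gate level.
#' @param posthoc_method `"bonferroni"` or `"tukey"`.
#' @return a `conn_group_stats` object: list of `omnibus` and `pairwise`
#'   data frames plus the settings used.
#' @export
run_group_analysis <- function(features, alpha = 0.05,
                               posthoc_method = c("bonferroni", "tukey")) {
  posthoc_method <- match.arg(posthoc_method)
  stopifnot(is.data.frame(features))
  bands <- mi_columns(features)
  omnibus <- list(); pairwise <- list()
  push <- function(res, what) {
    if (is.null(res)) {
      warning("comparison skipped (missing factor level or degenerate data): ",
              what)
      return(invisible())
    }
    omnibus[[length(omnibus) + 1L]] <<- res$omnibus
    if (!is.null(res$pairwise))
      pairwise[[length(pairwise) + 1L]] <<- res$pairwise
  }
  for (b in bands) {
    push(anova_one_factor(features, b, "stage", "all", alpha, posthoc_method),
         paste(b, "x stage"))
    for (st in intersect(STAGE_LEVELS, unique(features$stage))) {
      sub <- features[features$stage == st, ]
      push(anova_one_factor(sub, b, "age_group", st, alpha, posthoc_method),
           paste(b, "x age_group @", st))
      push(anova_one_factor(sub, b, "sex", st, alpha, posthoc_method),
           paste(b, "x sex @", st))
    }
  }
  structure(list(omnibus = do.call(rbind, omnibus),
                 pairwise = if (length(pairwise)) do.call(rbind, pairwise),
                 alpha = alpha, posthoc_method = posthoc_method,
                 correction_scope = "within each omnibus family"),
            class = "conn_group_stats")
}

#' @export
print.conn_group_stats <- function(x, ...) {
  cat("<conn_group_stats> omnibus one-way ANOVAs (", x$posthoc_method,
      " post-hoc, alpha = ", x$alpha, ")\n", sep = "")
  om <- x$omnibus
  om$F <- signif(om$F, 4); om$p <- signif(om$p, 3)
  print(om, row.names = FALSE)
  if (!is.null(x$pairwise))
    cat(nrow(x$pairwise), "post-hoc pairwise comparisons in $pairwise\n")
  invisible(x)
}

#' @export
summary.conn_group_stats <- function(object, ...) {
  om <- object$omnibus
  sig <- om[om$p < object$alpha, ]
  cat(nrow(sig), "of", nrow(om), "omnibus comparisons significant at",
      object$alpha, "\n")
  invisible(object)
}
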