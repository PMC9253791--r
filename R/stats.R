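#' Normality-gated group comparison
#'
#' The testing scheme of the electrophysiology analyses: Shapiro-Wilk per
#' group; when every group is consistent with normality, a two-sample (or
#' paired) t test for two groups --- with Levene's test informing the
#' equal-variance assumption --- or one-way ANOVA for more; otherwise the
#' Mann-Whitney rank-sum test (Kruskal-Wallis for more than two groups).
#' Constant groups, for which normality is undefined, fall to the rank
#' branch with a note.
#'
#' @param groups named list of numeric vectors (>= 3 values each).
#' @param paired paired design (two groups of equal length only)?
#' @param normality_alpha Shapiro-Wilk gate level (default 0.05).
#' @return `lg_group_test`: `branch`, `statistic`, `p_value`,
#'   `shapiro_p` (per group), `levene_p`, `note`.
#' @export
compare_groups <- function(groups, paired = FALSE, normality_alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, 1L) < 3))
    stop_lg("each group needs >= 3 values", class = "lipidgate_stats_error")
  note <- character()

  shapiro_p <- vapply(groups, function(g) {
    if (length(unique(g)) == 1) return(NA_real_)
    shapiro.test(g)$p.value
  }, 1.0)
  if (anyNA(shapiro_p))
    note <- c(note, "constant group: normality undefined, using rank test")
  normal <- !anyNA(shapiro_p) && all(shapiro_p > normality_alpha)

  gf <- factor(rep(names(groups), lengths(groups)))
  gv <- unlist(groups, use.names = FALSE)
  levene_p <- tryCatch(
    car::leveneTest(gv, gf)[["Pr(>F)"]][1],
    error = function(e) NA_real_)

  if (normal) {
    if (length(groups) == 2) {
      eq_var <- is.finite(levene_p) && levene_p > 0.05
      ht <- t.test(groups[[1]], groups[[2]], paired = paired,
                   var.equal = eq_var)
      branch <- if (paired) "paired t-test" else
        if (eq_var) "t-test" else "Welch t-test"
    } else {
      ht <- summary(aov(gv ~ gf))[[1]]
      branch <- "anova"
      ht <- list(statistic = c(F = ht[["F value"]][1]),
                 p.value = ht[["Pr(>F)"]][1])
    }
  } else {
    if (length(groups) == 2) {
      ht <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]],
                                         paired = paired))
      branch <- "mann-whitney"
    } else {
      ht <- stats::kruskal.test(groups)
      branch <- "kruskal-wallis"
    }
  }
  structure(list(branch = branch, statistic = unname(ht$statistic),
                 p_value = ht$p.value, shapiro_p = shapiro_p,
                 levene_p = levene_p,
                 note = if (length(note)) note else NULL),
            class = "lg_group_test")
}

#' @export
print.lg_group_test <- function(x, ...) {
  cat(sprintf("<lg_group_test> %s: statistic %.4g, p = %.4g\n",
              x$branch, x$statistic, x$p_value))
  if (!is.null(x$note)) cat(" note:", x$note, "\n")
  invisible(x)
}
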