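#' Bonferroni-adjusted significance level
#'
#' `alpha' = 1 - (1 - alpha)^(1/n)`: the per-test level that keeps the
#' family-wise error at `alpha` over `n` correlation tests.
#'
#' @param alpha family-wise significance level.
#' @param n_tests number of tests.
#' @return The adjusted level (about 0.0127 for `alpha = 0.05`, `n = 4`;
#'   reported rounded to 0.01 in the summaries).
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests = 4) {
  1 - (1 - alpha)^(1 / n_tests)
}

## Pearson when both variables pass Shapiro-Wilk normality at 0.05,
## Spearman otherwise.
.route_cor <- function(x, y, normality_alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(method = NA_character_, estimate = NA_real_, p = NA_real_,
                n = length(x)))
  normal <- function(z) {
    if (length(z) > 5000) z <- z[seq(1, length(z), length.out = 5000)]
    stats::shapiro.test(z)$p.value >= normality_alpha
  }
  use_pearson <- normal(x) && normal(y)
  ct <- suppressWarnings(stats::cor.test(
    x, y, method = if (use_pearson) "pearson" else "spearman", exact = FALSE))
  list(method = if (use_pearson) "pearson" else "spearman",
       estimate = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-speed correlation battery of the gait outcomes
#'
#' For each belt speed, correlates the hip quasi-stiffness `k_expt` with the
#' outcomes `T_expt`, `F_expt`, `b_expt` and `s_expt` across all steps and
#' subjects, using Pearson's coefficient when both variables are normally
#' distributed (Shapiro-Wilk at 0.05) and Spearman's rank coefficient
#' otherwise. A pooled correlation of `k_expt` with the step frequency
#' `1/tau_expt` across all speeds is appended. Significance is assessed at
#' the Bonferroni-adjusted level (reported at the rounded 0.01 level).
#'
#' @param records a `step_metrics` data.frame pooled over subjects (needs a
#'   `speed_label` column).
#' @param alpha family-wise significance level.
#' @param n_tests number of outcome tests per speed (for the adjustment).
#' @return An object of class `gait_correlations`: list with `table` (one row
#'   per speed x outcome, plus the pooled step-frequency row with
#'   `speed = "all"`), `alpha`, `alpha_prime`, `report_level`.
#' @export
correlation_analysis <- function(records, alpha = 0.05, n_tests = 4) {
  outcomes <- c("T_expt", "F_expt", "b_expt", "s_expt")
  speeds <- sort(unique(records$speed_label))
  rows <- list()
  for (sp in speeds) {
    d <- records[records$speed_label == sp, ]
    for (oc in outcomes) {
      r <- .route_cor(d$k_expt, d[[oc]])
      rows[[length(rows) + 1L]] <- data.frame(
        speed = as.character(sp), outcome = oc, method = r$method,
        estimate = r$estimate, p = r$p, n = r$n)
    }
  }
  r <- .route_cor(records$k_expt, 1 / records$tau_expt)
  rows[[length(rows) + 1L]] <- data.frame(
    speed = "all", outcome = "step_frequency", method = r$method,
    estimate = r$estimate, p = r$p, n = r$n)
  tab <- do.call(rbind, rows)
  ap <- bonferroni_alpha(alpha, n_tests)
  tab$significant <- !is.na(tab$p) & tab$p < round(ap, 2)
  structure(list(table = tab, alpha = alpha, alpha_prime = ap,
                 report_level = round(ap, 2)), class = "gait_correlations")
}

#' @export
print.gait_correlations <- function(x, ...) {
  cat(sprintf(
    "Correlation battery (alpha = %.2f, Bonferroni alpha' = %.5f, reported at %.2f)\n",
    x$alpha, x$alpha_prime, x$report_level))
  tab <- x$table
  tab$estimate <- round(tab$estimate, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
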