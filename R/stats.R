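#' Pearson correlation with t-based significance
#'
#' Thin, typed wrapper over [stats::cor.test()] used by the reporting
#' functions: Pearson's r, its square, and the two-sided p-value from the
#' t transform of r.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, neither constant.
#' @return An object of class `correlation_result` with fields `r`, `r2`,
#'   `n`, `p`, `statistic`, `df`. Has [tidy()] and [glance()] methods.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    stop_phenoplate("need at least 3 complete pairs", "correlation_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_phenoplate("constant input: correlation undefined", "correlation_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  structure(
    list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
         n = length(x), p = ct$p.value,
         statistic = unname(ct$statistic), df = unname(ct$parameter)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (r2 = %.4f), n = %d, p = %.3g\n",
              x$r, x$r2, x$n, x$p))
  invisible(x)
}

#' Descriptive summary: mean, sample SD and coefficient of variation
#'
#' The coefficient of variation is reported as a percentage,
#' `100 * sd / mean`, with the sample (n - 1) standard deviation. This is
#' the dispersion measure used to compare raw per-well absorbance against
#' seed-count-normalized absorbance.
#'
#' @param values Numeric vector, n >= 2.
#' @return One-row tibble: `mean`, `sd`, `cv_pct`, `n`. `cv_pct` is `NA`
#'   when the mean is zero.
#' @examples
#' describe_values(c(1, 2, 3))  # mean 2, sd 1, cv 50%
#' @export
describe_values <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    stop_phenoplate("need at least 2 finite values", "summary_error")
  }
  m <- mean(values); s <- sd(values)
  tibble(mean = m, sd = s,
         cv_pct = if (m != 0) 100 * s / m else NA_real_,
         n = length(values))
}

#' Coefficient of variation (%) from a mean and SD
#' @param mean,sd Summary statistics.
#' @return `100 * sd / mean`.
#' @export
cv_pct <- function(mean, sd) 100 * sd / mean

#' Dunn's rank-based post hoc test
#'
#' Pairwise z tests on mean ranks following a Kruskal-Wallis test, with the
#' usual tie correction, adjusted for multiple comparisons (Sidak by
#' default). No installed package exposes Dunn's test, so the standard
#' statistic is computed directly:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`
#' with tie term `T = sum(t^3 - t) / (12 (N - 1))`.
#'
#' @param values Numeric response.
#' @param groups Grouping factor/vector, parallel to `values`.
#' @param adjust `"sidak"`, `"bonferroni"`, `"holm"` or `"none"`.
#' @return Tibble, one row per group pair: `group1`, `group2`, `z`, `p`,
#'   `p_adj`.
#' @export
dunn_test <- function(values, groups, adjust = c("sidak", "bonferroni", "holm", "none")) {
  adjust <- arg_match(adjust)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    stop_phenoplate("need >= 2 groups with >= 2 observations each", "test_error")
  }
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, groups, mean)
  nn <- tapply(rk, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  res <- map(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / nn[[a]] + 1 / nn[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    tibble(group1 = a, group2 = b, z = z, p = 2 * pnorm(-abs(z)))
  }) |> list_rbind()
  res$p_adj <- switch(adjust,
    sidak = sidak_adjust(res$p),
    none = res$p,
    stats::p.adjust(res$p, method = adjust)
  )
  res
}

#' Log-linearization helper for exponential trends
#'
#' Fits `log(y) ~ x` by ordinary least squares, the standard linearization
#' for exponential growth or decay before assessing a trend with a t test.
#'
#' @param x Predictor.
#' @param y Strictly positive response.
#' @return List with `fit` (the `lm`), `rate` (slope on the log scale) and
#'   `r2`.
#' @export
log_linearize <- function(x, y) {
  if (any(y <= 0)) {
    stop_phenoplate("log-linearization requires strictly positive y", "domain_error")
  }
  fit <- lm(log(y) ~ x)
  list(fit = fit, rate = unname(coef(fit)[2]),
       r2 = summary(fit)$r.squared)
}
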