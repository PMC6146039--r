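#' @export
tidy.correlation_result <- function(x, ...) {
  tibble(estimate = x$r, r.squared = x$r2, statistic = x$statistic,
         df = x$df, p.value = x$p, n = x$n)
}

#' @export
glance.correlation_result <- function(x, ...) tidy(x)

#' @export
tidy.germination_calibration <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("(Intercept)", "abs_per_seed"),
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
}

#' @export
glance.germination_calibration <- function(x, ...) {
  tibble(r.squared = x$fit_r2, slope = x$slope, intercept = x$intercept,
         nobs = x$n)
}
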