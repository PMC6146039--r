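#' Per-seed formazan absorbance
#'
#' The germination assay reads each well at 570 nm (formazan) and 690 nm
#' (reference); the net absorbance `a570 - a690` is proportional to the
#' number of metabolically active (germinating) seeds. Dividing by the
#' counted seed number removes the dispensing variability in seeds per
#' well, which is what makes variants comparable.
#'
#' Wells with zero counted seeds get `abs_per_seed = NA` and are flagged;
#' negative net absorbance (reference exceeding test, i.e. blank-level
#' noise) is kept but flagged and excluded from summaries unless
#' `keep_negative = TRUE`.
#'
#' @param plate An [absorbance_plate()].
#' @param counts Seed counts: tibble with `well` and `seed_count`
#'   (e.g. from [count_plate_seeds()]).
#' @param treatments Optional [treatment_map()] joined onto the result.
#' @param keep_negative Include negative net absorbance in summaries?
#' @return Tibble, one row per well: `well`, `a570`, `a690`, `net_abs`,
#'   `seed_count`, `abs_per_seed`, `timepoint_h`, `flag`
#'   (`"ok"`, `"no_seeds"` or `"negative"`), `usable`, plus treatment
#'   columns when supplied.
#' @export
per_seed_absorbance <- function(plate, counts, treatments = NULL,
                                keep_negative = FALSE) {
  stopifnot(all(c("well", "seed_count") %in% names(counts)))
  missing <- setdiff(plate$well, counts$well)
  if (length(missing)) {
    stop_phenoplate(paste0("wells with readings but no seed counts: ",
                           paste(missing, collapse = ", ")),
                    "alignment_error")
  }
  out <- as_tibble(plate) |>
    left_join(counts[c("well", "seed_count")], by = "well") |>
    mutate(
      net_abs = .data$a570 - .data$a690,
      abs_per_seed = if_else(.data$seed_count >= 1,
                             .data$net_abs / .data$seed_count, NA_real_),
      timepoint_h = attr(plate, "timepoint_h") %||% NA_real_,
      flag = case_when(
        .data$seed_count == 0 ~ "no_seeds",
        .data$net_abs < 0 ~ "negative",
        TRUE ~ "ok"
      ),
      usable = .data$flag == "ok" | (.data$flag == "negative" & keep_negative)
    )
  if (!is.null(treatments)) {
    out <- left_join(out, as_tibble(treatments), by = "well")
  }
  out
}

#' Summarize a quantity per treatment variant
#'
#' Mean, sample SD and coefficient of variation of `net_abs` or
#' `abs_per_seed` over the usable wells of each variant. Comparing the two
#' CVs is the core normalization check: counting seeds should shrink the
#' dispersion severalfold.
#'
#' @param records Output of [per_seed_absorbance()].
#' @param by `"abs_per_seed"` (default) or `"net_abs"`.
#' @param group_cols Columns defining a variant; defaults to whichever of
#'   `compound`, `conc_mM`, `condition` are present (none present = one
#'   overall summary).
#' @return Tibble: grouping columns plus `n_wells`, `mean`, `sd`, `cv_pct`.
#' @export
summarize_variant <- function(records, by = c("abs_per_seed", "net_abs"),
                              group_cols = NULL) {
  by <- arg_match(by)
  group_cols <- group_cols %||%
    intersect(c("compound", "conc_mM", "condition"), names(records))
  usable <- records |>
    filter(.data$usable %||% TRUE, is.finite(.data[[by]]))
  if (nrow(usable) < 2) {
    stop_phenoplate("need at least 2 usable records to summarize", "summary_error")
  }
  usable |>
    group_by(across(dplyr::all_of(group_cols))) |>
    summarise(
      n_wells = n(),
      mean = mean(.data[[by]]),
      sd = sd(.data[[by]]),
      .groups = "drop"
    ) |>
    mutate(cv_pct = if_else(.data$mean != 0, 100 * .data$sd / .data$mean, NA_real_))
}

#' Fit a linear calibration from per-seed absorbance to germination rate
#'
#' Per-seed absorbance correlates linearly with the fraction of seeds
#' germinated; this fits that map by ordinary least squares on user-supplied
#' calibration pairs (the coefficients are assay-specific and must be fit,
#' not assumed). Predictions are clamped to `[0, 100]` %.
#'
#' @param pairs Data frame with columns `abs_per_seed` and
#'   `germination_pct`; at least 3 rows, non-constant `abs_per_seed`.
#' @return Object of class `germination_calibration`: `slope`, `intercept`,
#'   `fit_r2`, and the underlying `lm` fit. Has [predict()], [tidy()] and
#'   [glance()] methods.
#' @export
fit_germination_calibration <- function(pairs) {
  need <- c("abs_per_seed", "germination_pct")
  if (!all(need %in% names(pairs))) {
    stop_phenoplate("calibration pairs need columns abs_per_seed, germination_pct",
                    "format_error")
  }
  pairs <- pairs[complete.cases(pairs[need]), ]
  if (nrow(pairs) < 3) {
    stop_phenoplate("need at least 3 calibration pairs", "fit_error")
  }
  if (sd(pairs$abs_per_seed) == 0) {
    stop_phenoplate("abs_per_seed is constant: calibration undefined", "fit_error")
  }
  fit <- lm(germination_pct ~ abs_per_seed, data = pairs)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         fit_r2 = summary(fit)$r.squared, n = nrow(pairs), fit = fit),
    class = "germination_calibration"
  )
}

#' @export
print.germination_calibration <- function(x, ...) {
  cat(sprintf("germination %% = %.4g + %.4g * abs_per_seed  (r2 = %.4f, n = %d)\n",
              x$intercept, x$slope, x$fit_r2, x$n))
  invisible(x)
}

#' @export
predict.germination_calibration <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$abs_per_seed else newdata
  pmin(100, pmax(0, object$intercept + object$slope * x))
}

#' Compare treatment variants to their control
#'
#' Group comparison of a well-level quantity across variants, either by
#' the Kruskal-Wallis test with Dunn's post hoc z tests and Sidak
#' adjustment (default, matching rank-based reporting of germination
#' data), or one-way ANOVA followed by Sidak-adjusted pairwise contrasts
#' (via \pkg{emmeans}).
#'
#' @param records Well-level tibble (e.g. from [per_seed_absorbance()]).
#' @param value Name of the response column (default `"abs_per_seed"`).
#' @param group Name of the grouping column (default `"group"`); build one
#'   with e.g. `paste(compound, conc_mM)`.
#' @param test `"kruskal_dunn_sidak"` or `"anova_dunn_sidak"`.
#' @param control Optional label of the control group; when given, only
#'   contrasts against it are returned.
#' @return Tibble of pairwise contrasts: `group1`, `group2`, `statistic`,
#'   `p`, `p_adj`, `sig_05`, `sig_01`, `sig_001`, with the omnibus test's
#'   statistic and p-value as attributes `omnibus_statistic`, `omnibus_p`.
#' @export
compare_to_control <- function(records, value = "abs_per_seed", group = "group",
                               test = c("kruskal_dunn_sidak", "anova_dunn_sidak"),
                               control = NULL) {
  test <- arg_match(test)
  v <- records[[value]]; g <- records[[group]]
  if (is.null(v) || is.null(g)) {
    stop_phenoplate("value/group columns not found in records", "format_error")
  }
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]; g <- factor(g[ok])
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    stop_phenoplate("need >= 2 groups with >= 2 observations each", "test_error")
  }
  if (test == "kruskal_dunn_sidak") {
    om <- kruskal.test(v, g)
    post <- dunn_test(v, g, adjust = "sidak") |>
      rename(statistic = "z")
    om_stat <- unname(om$statistic); om_p <- om$p.value
  } else {
    df <- data.frame(v = v, g = g)
    fit <- aov(v ~ g, data = df)
    em <- emmeans::emmeans(fit, "g")
    ct <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "sidak"))
    nm <- strsplit(as.character(ct$contrast), " - ")
    post <- tibble(
      group1 = vapply(nm, `[`, "", 1), group2 = vapply(nm, `[`, "", 2),
      statistic = ct$t.ratio, p = NA_real_, p_adj = ct$p.value
    )
    sm <- summary(fit)[[1]]
    om_stat <- sm$`F value`[1]; om_p <- sm$`Pr(>F)`[1]
  }
  if (!is.null(control)) {
    post <- post |>
      filter(.data$group1 == control | .data$group2 == control) |>
      mutate(
        other = if_else(.data$group1 == control, .data$group2, .data$group1),
        group1 = control, group2 = .data$other
      ) |>
      select(-"other")
  }
  post <- post |>
    mutate(sig_05 = .data$p_adj < 0.05, sig_01 = .data$p_adj < 0.01,
           sig_001 = .data$p_adj < 0.001)
  attr(post, "omnibus_statistic") <- om_stat
  attr(post, "omnibus_p") <- om_p
  attr(post, "test") <- test
  post
}
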