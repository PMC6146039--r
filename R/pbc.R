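#' Log2 trait ratio of a variant against its matched control
#'
#' @param variant_value,control_value Strictly positive trait values.
#' @param what Optional trait/variant name used in error messages.
#' @return `log2(variant_value / control_value)` (vectorized).
#' @export
trait_log2_ratio <- function(variant_value, control_value, what = "trait") {
  bad <- !is.finite(variant_value) | !is.finite(control_value) |
    variant_value <= 0 | control_value <= 0
  if (any(bad)) {
    stop_phenoplate(paste0("non-positive or missing value for ", what,
                           ": log2 ratio undefined"), "domain_error")
  }
  log2(variant_value / control_value)
}

pbc_trait_names <- function(condition) {
  ## establishment is scored in the no-salt assay only: under stress the
  ## seedlings were transferred before the stress was applied, so the
  ## stress-condition index sums germination, growth and colour
  if (identical(condition, "control")) {
    c("germination", "establishment", "growth", "color")
  } else {
    c("germination", "growth", "color")
  }
}

#' Compute the Plant Biostimulant Characterization (PBC) index
#'
#' For every variant (compound x concentration) under every growth
#' condition, each trait is compared with the untreated control of the
#' same condition as a log2 ratio; the PBC index is the sum of those
#' ratios — a single signed score per variant x condition. Positive
#' scores indicate biostimulant activity, negative scores inhibition,
#' with a dead zone of `epsilon` log2 units labelled `neutral` to keep
#' labels stable under measurement noise.
#'
#' Under the control condition four traits contribute (germination,
#' establishment, growth, colour); under the salt-stress conditions
#' three (establishment is only measured without salt). Scores are
#' therefore comparable within, not across, conditions.
#'
#' @param traits Trait table: tibble with columns `compound`, `conc_mM`,
#'   `condition` and the trait columns `germination`, `establishment`,
#'   `growth`, `color` (establishment may be `NA` under stress). The
#'   control rows have `compound == "none"`. Trait values are per-variant
#'   means (ratio of means, not mean of ratios).
#' @param epsilon Dead-zone half-width in log2 units (default 0.1).
#' @return Tibble, one row per variant x condition: `compound`, `conc_mM`,
#'   `condition`, `log2_germination`, `log2_establishment`, `log2_growth`,
#'   `log2_color`, `pbc`, `label` (`biostimulant`/`inhibitor`/`neutral`).
#' @export
compute_pbc <- function(traits, epsilon = 0.1) {
  need <- c("compound", "conc_mM", "condition")
  stopifnot(all(need %in% names(traits)))
  controls <- traits |> filter(.data$compound == "none")
  variants <- traits |> filter(.data$compound != "none")
  missing <- setdiff(unique(variants$condition), controls$condition)
  if (length(missing)) {
    stop_phenoplate(paste0("no matched control for condition(s): ",
                           paste(missing, collapse = ", ")), "pairing_error")
  }
  map(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    ctl <- controls[controls$condition == v$condition, ][1, ]
    tr <- pbc_trait_names(v$condition)
    l2 <- setNames(rep(NA_real_, 4),
                   c("germination", "establishment", "growth", "color"))
    for (t in tr) {
      l2[[t]] <- trait_log2_ratio(v[[t]], ctl[[t]],
                                  what = sprintf("%s (%s %g mM, %s)",
                                                 t, v$compound, v$conc_mM,
                                                 v$condition))
    }
    pbc <- sum(l2[tr])
    tibble(
      compound = v$compound, conc_mM = v$conc_mM, condition = v$condition,
      log2_germination = l2[["germination"]],
      log2_establishment = l2[["establishment"]],
      log2_growth = l2[["growth"]],
      log2_color = l2[["color"]],
      pbc = pbc,
      label = case_when(pbc > epsilon ~ "biostimulant",
                        pbc < -epsilon ~ "inhibitor",
                        TRUE ~ "neutral")
    )
  }) |> list_rbind()
}

#' Classify a compound's mode of action from its PBC profile
#'
#' Operationalizes the three narrative categories — growth
#' promotor/inhibitor, stress alleviator, combined action — from the PBC
#' scores of one compound x concentration across growth conditions:
#' \itemize{
#'   \item `combined`: positive PBC (beyond `epsilon`) both without salt
#'     and under at least one stress level;
#'   \item `growth_promotor`: positive only without salt;
#'   \item `stress_alleviator`: positive only under stress;
#'   \item `growth_inhibitor`: negative PBC without salt (and no stress
#'     alleviation);
#'   \item `none`: everything within the dead zone.
#' }
#'
#' @param records A [compute_pbc()] table (any number of compounds).
#' @param epsilon Dead-zone half-width, matching [compute_pbc()].
#' @return Tibble `compound`, `conc_mM`, `mode`.
#' @export
classify_mode <- function(records, epsilon = 0.1) {
  records |>
    group_by(.data$compound, .data$conc_mM) |>
    summarise(mode = {
      ctl <- .data$pbc[.data$condition == "control"]
      if (length(ctl) != 1) {
        stop_phenoplate("each compound x concentration needs exactly one control-condition record",
                        "classification_error")
      }
      stress <- .data$pbc[.data$condition != "control"]
      if (!length(stress)) {
        stop_phenoplate("need at least one stress-condition record", "classification_error")
      }
      ctl_up <- ctl > epsilon
      stress_up <- any(stress > epsilon)
      if (ctl_up && stress_up) "combined"
      else if (ctl_up) "growth_promotor"
      else if (stress_up) "stress_alleviator"
      else if (ctl < -epsilon) "growth_inhibitor"
      else "none"
    }, .groups = "drop")
}

#' Export PBC parallel-coordinate and radar-chart data
#'
#' Writes `<prefix>_parallel_coords.csv` (one row per variant x condition,
#' one column per trait log2 ratio plus the summed index) and
#' `<prefix>_radar.json` (per condition: axes = concentrations, one series
#' of PBC values per compound — the structure of a radar chart grouped by
#' condition).
#'
#' @param records A [compute_pbc()] table.
#' @param prefix Output path prefix.
#' @param modes Optional [classify_mode()] table merged into the CSV.
#' @return Named character vector of the files written, invisibly.
#' @export
export_charts <- function(records, prefix, modes = NULL) {
  if (nrow(records) == 0) {
    stop_phenoplate("no PBC records to export", "format_error")
  }
  pc_path <- paste0(prefix, "_parallel_coords.csv")
  radar_path <- paste0(prefix, "_radar.json")
  out <- records
  if (!is.null(modes)) out <- left_join(out, modes, by = c("compound", "conc_mM"))
  write_results_table(out, pc_path)
  radar <- records |>
    group_by(.data$condition) |>
    nest() |>
    ungroup() |>
    pmap(function(condition, data) {
      concs <- sort(unique(data$conc_mM))
      series <- data |>
        group_by(.data$compound) |>
        nest() |>
        pmap(function(compound, data) {
          list(compound = compound,
               pbc = data$pbc[match(concs, data$conc_mM)])
        })
      list(condition = condition, axes_conc_mM = concs, series = series)
    })
  jsonlite::write_json(radar, radar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(parallel_coords = pc_path, radar = radar_path))
}

#' Build the trait table feeding the PBC index
#'
#' Averages each trait over the replicate wells of each variant
#' (ratio of means): germination activity as mean per-seed absorbance,
#' establishment as mean time-zero green area (control condition only),
#' growth capacity as mean final green area of alive plants, and colour
#' as mean GLI.
#'
#' @param germination Output of [per_seed_absorbance()] with treatment
#'   columns.
#' @param growth Output of [summarize_growth()] with treatment columns.
#' @param color Output of [measure_plate_indices()] with treatment columns.
#' @return Trait tibble for [compute_pbc()]: `compound`, `conc_mM`,
#'   `condition`, `germination`, `establishment`, `growth`, `color`.
#' @export
build_trait_table <- function(germination, growth, color) {
  key <- c("compound", "conc_mM", "condition")
  germ <- germination |>
    filter(.data$usable, is.finite(.data$abs_per_seed)) |>
    group_by(across(dplyr::all_of(key))) |>
    summarise(germination = mean(.data$abs_per_seed), .groups = "drop")
  gr <- growth |>
    group_by(across(dplyr::all_of(key))) |>
    summarise(
      establishment = mean(.data$t0_area_px, na.rm = TRUE),
      growth = mean(.data$final_area_px[.data$status == "alive"], na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(establishment = if_else(.data$condition == "control",
                                   .data$establishment, NA_real_))
  col <- color |>
    filter(!.data$empty, is.finite(.data$gli)) |>
    group_by(across(dplyr::all_of(key))) |>
    summarise(color = mean(.data$gli), .groups = "drop")
  germ |>
    inner_join(gr, by = key) |>
    inner_join(col, by = key) |>
    arrange(.data$condition, .data$compound, .data$conc_mM)
}
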