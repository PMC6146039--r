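#' Segment the rosette in one well
#'
#' Plant pixels are identified by the excess-green score `2G - R - B`
#' (channels in `[0, 1]`): green tissue scores high, agar and plate
#' plastic near zero. Pixels above `threshold` inside the well interior
#' form the candidate mask; the largest 8-connected component is kept (one
#' plant per well) and its holes are filled. An empty mask is a valid
#' result (no plant, or a dead brown one).
#'
#' @param image A [plate_image()] frame of the 48-well plate.
#' @param well Well label.
#' @param threshold Excess-green cutoff, default 0.10.
#' @return Object of class `plant_mask`: list with `well`, `timestamp_h`,
#'   `mask` (logical matrix over the well bounding box), `offset`,
#'   `green_area_px`.
#' @export
segment_rosette <- function(image, well, threshold = 0.10) {
  stopifnot(inherits(image, "plate_image"))
  cw <- crop_well(image, well)
  exg <- 2 * cw$pixels[, , 2] - cw$pixels[, , 1] - cw$pixels[, , 3]
  mask <- cw$inside & (exg > threshold)
  if (any(mask)) mask <- fill_holes(largest_component(mask)) & cw$inside
  structure(
    list(well = cw$region$well, timestamp_h = image$timestamp_h,
         mask = mask, offset = c(cw$region$x0 - 1, cw$region$y0 - 1),
         green_area_px = sum(mask)),
    class = "plant_mask"
  )
}

#' @export
print.plant_mask <- function(x, ...) {
  cat(sprintf("<plant_mask> well %s, t = %.4g h, green area %d px\n",
              x$well, x$timestamp_h, x$green_area_px))
  invisible(x)
}

#' Measure green area across a time-lapse image series
#'
#' Segments every well in every frame and returns the long table of
#' green areas that feeds [build_timeseries()].
#'
#' @param images List of [plate_image()] frames of one plate (any order;
#'   timestamps must be distinct).
#' @param wells Wells to process (default all).
#' @param threshold Excess-green cutoff passed to [segment_rosette()].
#' @param keep_masks Also return the mask objects (for [plant_indices()]).
#' @return Tibble `well`, `timestamp_h`, `green_area_px`; with
#'   `keep_masks = TRUE`, attribute `masks` holds the nested list
#'   `masks[[timestamp]][[well]]`.
#' @export
measure_plate_growth <- function(images, wells = NULL, threshold = 0.10,
                                 keep_masks = FALSE) {
  stopifnot(length(images) >= 1, all(map_chr(images, ~ class(.x)[1]) == "plate_image"))
  images <- images[order(map_dbl(images, "timestamp_h"))]
  wells <- wells %||% well_labels(images[[1]]$layout)
  masks <- map(images, function(img) {
    ms <- map(wells, ~ segment_rosette(img, .x, threshold = threshold))
    names(ms) <- wells
    ms
  })
  names(masks) <- map_chr(images, ~ format(.x$timestamp_h))
  out <- map(masks, function(frame) {
    tibble(well = wells,
           timestamp_h = map_dbl(frame, "timestamp_h"),
           green_area_px = map_int(frame, "green_area_px"))
  }) |> list_rbind()
  if (keep_masks) attr(out, "masks") <- masks
  out
}

#' Assemble per-well growth time series with a dead-plant policy
#'
#' Orders each well's `(timestamp, green area)` points, labels the series
#' `dead` when the area stays below `min_alive_area` for the last two or
#' more consecutive points (a shrivelled or fully chlorotic plant no longer
#' contributes green pixels), and truncates dead series at the last alive
#' point. Requires at least two timepoints per well.
#'
#' @param areas Tibble with `well`, `timestamp_h`, `green_area_px`
#'   (from [measure_plate_growth()] or a generator manifest).
#' @param min_alive_area Pixels; below this a plant is considered not
#'   detectably alive (default 25).
#' @param treatments Optional [treatment_map()] joined on.
#' @return Tibble `well`, `timestamp_h`, `green_area_px`, `status`
#'   (`"alive"`/`"dead"`), dead tails removed, plus treatment columns if
#'   supplied.
#' @export
build_timeseries <- function(areas, min_alive_area = 25, treatments = NULL) {
  need <- c("well", "timestamp_h", "green_area_px")
  stopifnot(all(need %in% names(areas)))
  if (anyDuplicated(areas[c("well", "timestamp_h")])) {
    stop_phenoplate("duplicated timestamp within a well", "data_error")
  }
  per_well <- areas |>
    as_tibble() |>
    arrange(.data$well, .data$timestamp_h) |>
    group_by(.data$well) |>
    nest() |>
    ungroup()
  out <- per_well |>
    mutate(data = map(.data$data, function(d) {
      if (nrow(d) < 2) {
        stop_phenoplate("each well needs at least 2 timepoints", "data_error")
      }
      below <- d$green_area_px < min_alive_area
      ## length of the trailing run of below-threshold points
      tail_run <- 0
      for (i in rev(seq_len(nrow(d)))) {
        if (below[i]) tail_run <- tail_run + 1 else break
      }
      if (tail_run >= 2) {
        d$status <- "dead"
        keep <- nrow(d) - tail_run
        d <- d[seq_len(max(keep, 1)), ]
      } else {
        d$status <- "alive"
      }
      d
    })) |>
    unnest("data") |>
    select("well", "timestamp_h", "green_area_px", "status")
  if (!is.null(treatments)) {
    out <- left_join(out, as_tibble(treatments), by = "well")
  }
  out
}

#' Relative growth rate per imaging interval
#'
#' For each consecutive pair of timepoints of each well,
#' `RGR = (ln A_ti - ln A_ti-1) / (ti - ti-1)` in
#' pixel·pixel^-1·h^-1 (or ·day^-1 with `unit = "per_day"`, exactly 24
#' times the hourly value). Unequal spacing (6 h daytime vs 18 h
#' overnight intervals) is handled exactly by the denominator; no
#' resampling. All retained areas must be positive.
#'
#' @param series Tibble from [build_timeseries()] (or any tibble with
#'   `well`, `timestamp_h`, `green_area_px`).
#' @param unit `"per_hour"` (default) or `"per_day"`.
#' @return Tibble, one row per interval: `well`, `t_start_h`, `t_end_h`,
#'   `rgr`.
#' @export
rgr <- function(series, unit = c("per_hour", "per_day")) {
  unit <- arg_match(unit)
  bad <- series |> filter(.data$green_area_px <= 0)
  if (nrow(bad)) {
    stop_phenoplate(paste0(
      "non-positive green area at retained point(s): ",
      paste(sprintf("%s@%gh", bad$well, bad$timestamp_h), collapse = ", ")),
      "domain_error")
  }
  out <- series |>
    as_tibble() |>
    arrange(.data$well, .data$timestamp_h) |>
    group_by(.data$well) |>
    mutate(
      t_start_h = lag(.data$timestamp_h),
      rgr = (log(.data$green_area_px) - lag(log(.data$green_area_px))) /
        (.data$timestamp_h - lag(.data$timestamp_h))
    ) |>
    ungroup() |>
    filter(!is.na(.data$rgr)) |>
    select("well", "t_start_h", t_end_h = "timestamp_h", "rgr")
  if (unit == "per_day") out$rgr <- out$rgr * 24
  out
}

#' Seedling establishment area
#'
#' The green area at the earliest timepoint of each series — the size of
#' the transferred seedling at time zero of the rosette assay, used as the
#' establishment trait. Returned for dead series too (the plant was alive
#' at transfer).
#'
#' @param series Tibble with `well`, `timestamp_h`, `green_area_px`.
#' @return Tibble `well`, `t0_h`, `t0_area_px`.
#' @export
establishment_area <- function(series) {
  if (nrow(series) == 0) {
    stop_phenoplate("empty series", "data_error")
  }
  series |>
    as_tibble() |>
    group_by(.data$well) |>
    arrange(.data$timestamp_h, .by_group = TRUE) |>
    summarise(t0_h = first(.data$timestamp_h),
              t0_area_px = first(.data$green_area_px),
              .groups = "drop")
}

#' Per-well growth summary
#'
#' Combines establishment area, final area, mean interval RGR (per day,
#' unweighted mean over intervals) and status into the per-well record
#' used for trait building and reporting. Dead plants keep their
#' establishment area but get `NA` growth fields.
#'
#' @param series Tibble from [build_timeseries()].
#' @return Tibble: `well`, `t0_area_px`, `final_area_px`, `mean_rgr_day`,
#'   `n_intervals`, `status`, plus any treatment columns present in
#'   `series`.
#' @export
summarize_growth <- function(series) {
  extra <- intersect(c("compound", "conc_mM", "condition"), names(series))
  status <- series |> distinct(.data$well, .data$status)
  est <- establishment_area(series)
  alive <- series |> filter(.data$status == "alive")
  growth <- if (nrow(alive)) {
    fin <- alive |>
      group_by(.data$well) |>
      summarise(final_area_px = last(.data$green_area_px[order(.data$timestamp_h)]),
                .groups = "drop")
    mr <- rgr(alive, unit = "per_day") |>
      group_by(.data$well) |>
      summarise(mean_rgr_day = mean(.data$rgr), n_intervals = n(), .groups = "drop")
    left_join(fin, mr, by = "well")
  } else {
    tibble(well = character(), final_area_px = integer(),
           mean_rgr_day = numeric(), n_intervals = integer())
  }
  out <- status |>
    left_join(est, by = "well") |>
    left_join(growth, by = "well") |>
    select("well", "t0_area_px", "final_area_px", "mean_rgr_day",
           "n_intervals", "status")
  if (length(extra)) {
    out <- left_join(out, distinct(series[c("well", extra)]), by = "well")
  }
  out
}

#' Mortality fraction per variant
#'
#' Fraction of wells whose series ended dead, reported alongside growth
#' summaries (dead plants are excluded from RGR means but counted here).
#'
#' @param series Tibble from [build_timeseries()] with treatment columns.
#' @param group_cols Variant-defining columns (default: those of
#'   `compound`, `conc_mM`, `condition` present).
#' @return Tibble: grouping columns, `n_plants`, `n_dead`, `mortality`.
#' @export
mortality_fraction <- function(series, group_cols = NULL) {
  group_cols <- group_cols %||%
    intersect(c("compound", "conc_mM", "condition"), names(series))
  series |>
    distinct(across(dplyr::all_of(c("well", group_cols, "status")))) |>
    group_by(across(dplyr::all_of(group_cols))) |>
    summarise(n_plants = n(), n_dead = sum(.data$status == "dead"),
              mortality = .data$n_dead / .data$n_plants, .groups = "drop")
}
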