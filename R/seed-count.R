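#' Segment seeds inside one well
#'
#' Seeds are darker than the agarose background in all three colour
#' channels. Pixels inside the well interior whose R, G and B values all
#' fall below per-channel thresholds form the foreground; holes are filled
#' and objects smaller than the debris floor are removed. Objects touching
#' the well boundary are retained.
#'
#' By default each channel's threshold is an Otsu split of that channel
#' within the well region, with a contrast guard: when foreground and
#' background means differ by less than `min_contrast` the well is treated
#' as empty (an Otsu split of a uniform background would otherwise invent
#' foreground out of sensor noise).
#'
#' @param image A [plate_image()] of the pre-germination (0 h) scan.
#' @param well Well label.
#' @param thresholds Optional numeric length-3 `(R, G, B)` upper bounds
#'   overriding the Otsu defaults.
#' @param min_area Debris floor in pixels; objects below it are dropped.
#'   Defaults to `0.25 * avg_seed_area_px` when that is supplied, else 6 px.
#' @param avg_seed_area_px Optional average single-seed area, used only for
#'   the default `min_area`.
#' @param min_contrast Minimum foreground/background mean separation for the
#'   Otsu route (default 0.15).
#' @return A logical matrix covering the well's bounding box, with
#'   attribute `offset = c(x0 - 1, y0 - 1)` locating it in the full image.
#' @export
segment_seeds <- function(image, well, thresholds = NULL, min_area = NULL,
                          avg_seed_area_px = NULL, min_contrast = 0.15) {
  stopifnot(inherits(image, "plate_image"))
  cw <- crop_well(image, well)
  if (is.null(min_area)) {
    min_area <- if (!is.null(avg_seed_area_px)) 0.25 * avg_seed_area_px else 6
  }
  mask <- cw$inside
  for (ch in 1:3) {
    vals <- cw$pixels[, , ch]
    th <- if (!is.null(thresholds)) {
      thresholds[ch]
    } else {
      otsu_threshold(vals[cw$inside], min_contrast = min_contrast)
    }
    mask <- mask & if (is.na(th)) FALSE else (vals < th)
  }
  if (any(mask)) {
    mask <- fill_holes(mask) & cw$inside
    mask <- remove_small(mask, min_area)
  }
  attr(mask, "offset") <- c(cw$region$x0 - 1, cw$region$y0 - 1)
  attr(mask, "well") <- cw$region$well
  mask
}

#' Measure connected objects in a binary mask
#'
#' One row per 8-connected component with its pixel area, convex-hull
#' pixel area, solidity (`area_px / convex_area_px`, in `(0, 1]`) and
#' centroid. Solidity is the single/cluster discriminator: convex single
#' seeds sit near 1, clusters of touching seeds fall below it.
#'
#' @param mask Logical matrix (typically from [segment_seeds()]).
#' @return Tibble with columns `object_id`, `area_px`, `convex_area_px`,
#'   `solidity`, `centroid_x`, `centroid_y` (empty for an empty mask).
#' @export
measure_objects <- function(mask) {
  offset <- attr(mask, "offset") %||% c(0, 0)
  out <- component_stats(mask, offset = offset)
  w <- attr(mask, "well")
  if (!is.null(w)) out <- mutate(out, well = w, .before = 1)
  out
}

#' Count seeds from measured objects
#'
#' Objects with solidity at or above `solidity_threshold` count as one
#' seed. Lower-solidity objects are clusters; their seed number is the
#' object area divided by the average single-seed area, rounded to the
#' nearest integer (halves away from zero) with a floor of two — an object
#' flagged as a cluster cannot hold fewer than two seeds.
#'
#' @param objects Tibble from [measure_objects()].
#' @param avg_seed_area_px Average area of a single seed in pixels
#'   (from [estimate_avg_seed_area()] or a manual value).
#' @param solidity_threshold Single/cluster cut, default 0.9.
#' @return The `objects` tibble with `is_cluster` and `estimated_seeds`
#'   columns, plus attributes `seed_count` (their sum) and
#'   `avg_seed_area_px`.
#' @export
count_seeds <- function(objects, avg_seed_area_px, solidity_threshold = 0.9) {
  if (!is.numeric(avg_seed_area_px) || avg_seed_area_px <= 0) {
    stop_phenoplate("avg_seed_area_px must be positive", "parameter_error")
  }
  if (solidity_threshold <= 0 || solidity_threshold > 1) {
    stop_phenoplate("solidity_threshold must be in (0, 1]", "parameter_error")
  }
  objects <- objects |>
    mutate(
      is_cluster = .data$solidity < solidity_threshold,
      estimated_seeds = if_else(
        .data$is_cluster,
        pmax(2L, as.integer(round_half_away(.data$area_px / avg_seed_area_px))),
        1L
      )
    )
  attr(objects, "seed_count") <- sum(objects$estimated_seeds)
  attr(objects, "avg_seed_area_px") <- avg_seed_area_px
  objects
}

#' Estimate the average single-seed area
#'
#' The reference area used to split clusters: the median area of
#' high-solidity (single-seed) objects pooled over many wells. Requires at
#' least `min_n` such objects; with fewer, segmentation is unreliable and a
#' manual value should be supplied instead.
#'
#' @param objects Tibble of measured objects pooled across wells.
#' @param solidity_floor Objects at or above this solidity are taken as
#'   singles (default 0.9).
#' @param min_n Minimum number of singles required (default 10).
#' @return Median single-seed area in pixels.
#' @export
estimate_avg_seed_area <- function(objects, solidity_floor = 0.9, min_n = 10) {
  singles <- objects$area_px[objects$solidity >= solidity_floor]
  if (length(singles) < min_n) {
    stop_phenoplate(sprintf(
      "only %d high-solidity objects (need >= %d); supply avg_seed_area_px manually",
      length(singles), min_n), "estimation_error")
  }
  median(singles)
}

#' Count seeds in every well of a plate scan
#'
#' Runs [segment_seeds()], [measure_objects()] and [count_seeds()] over all
#' wells. When `avg_seed_area_px` is `NULL` it is estimated from the plate
#' itself ([estimate_avg_seed_area()] over a first segmentation pass), then
#' counting is re-run with the matched debris floor.
#'
#' @inheritParams segment_seeds
#' @inheritParams count_seeds
#' @param wells Wells to process (default: all wells of the layout).
#' @return Tibble, one row per well: `plate_id`, `well`, `n_objects`,
#'   `n_clusters`, `seed_count`, `avg_seed_area_used`. The per-object
#'   table is attached as attribute `objects`.
#' @export
count_plate_seeds <- function(image, avg_seed_area_px = NULL,
                              solidity_threshold = 0.9, thresholds = NULL,
                              wells = NULL, min_contrast = 0.15) {
  stopifnot(inherits(image, "plate_image"))
  wells <- wells %||% well_labels(image$layout)
  measure_all <- function(avg_area) {
    map(wells, function(w) {
      segment_seeds(image, w, thresholds = thresholds,
                    avg_seed_area_px = avg_area,
                    min_contrast = min_contrast) |>
        measure_objects()
    }) |> list_rbind()
  }
  objects <- measure_all(avg_seed_area_px)
  if (is.null(avg_seed_area_px)) {
    avg_seed_area_px <- estimate_avg_seed_area(objects,
                                               solidity_floor = solidity_threshold)
    objects <- measure_all(avg_seed_area_px)
  }
  counted <- count_seeds(objects, avg_seed_area_px, solidity_threshold)
  out <- tibble(well = wells) |>
    left_join(
      counted |>
        group_by(.data$well) |>
        summarise(n_objects = n(), n_clusters = sum(.data$is_cluster),
                  seed_count = sum(.data$estimated_seeds)),
      by = "well"
    ) |>
    mutate(
      across(c("n_objects", "n_clusters", "seed_count"),
             ~ if_else(is.na(.x), 0L, as.integer(.x))),
      plate_id = image$layout$plate_id,
      avg_seed_area_used = avg_seed_area_px,
      .before = 1
    ) |>
    select("plate_id", "well", "n_objects", "n_clusters", "seed_count",
           "avg_seed_area_used")
  attr(out, "objects") <- counted
  out
}
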