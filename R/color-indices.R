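#' RGB vegetation indices per pixel
#'
#' Three leaf-colour indices computed from visible bands only, each
#' invariant to overall brightness (`(r,g,b) -> (cr,cg,cb)`):
#' \describe{
#'   \item{NGRDI}{normalized green-red difference, `(G - R) / (G + R)`}
#'   \item{GLI}{green leaf index, `(2G - R - B) / (2G + R + B)`}
#'   \item{VARI}{visible atmospherically resistant index,
#'     `(G - R) / (G + R - B)`}
#' }
#' NGRDI and GLI are bounded in `[-1, 1]`; VARI is unbounded near its
#' singularity `G + R = B`. Any index whose denominator is within `1e-9`
#' of zero is returned as `NA` (undefined, excluded from means and
#' tallied) rather than clipped.
#'
#' @param r,g,b Numeric vectors of channel values in `[0, 1]` (recycled to
#'   a common length).
#' @return Tibble with columns `ngrdi`, `gli`, `vari`.
#' @examples
#' pixel_indices(0.2, 0.6, 0.4)  # ngrdi 0.5, gli 0.375, vari 1
#' @export
pixel_indices <- function(r, g, b) {
  n <- max(length(r), length(g), length(b))
  r <- rep_len(as.numeric(r), n)
  g <- rep_len(as.numeric(g), n)
  b <- rep_len(as.numeric(b), n)
  vals <- c(r, g, b)
  if (anyNA(vals) || min(vals) < 0 || max(vals) > 1) {
    stop_phenoplate("channel values must be within [0, 1]", "domain_error")
  }
  safe_ratio <- function(num, den) if_else(abs(den) < 1e-9, NA_real_, num / den)
  tibble(
    ngrdi = safe_ratio(g - r, g + r),
    gli = safe_ratio(2 * g - r - b, 2 * g + r + b),
    vari = safe_ratio(g - r, g + r - b)
  )
}

#' Mean vegetation indices over one plant mask
#'
#' Extracts the channel values of every pixel inside the plant mask,
#' computes the three indices per pixel, and averages them per plant.
#' Pixels where VARI is undefined are excluded from the VARI mean and
#' counted in `n_undefined_px`. An empty mask yields an all-`NA` record
#' flagged `empty`, not an error (dead plants have no mask).
#'
#' @param image The [plate_image()] the mask was segmented from.
#' @param mask A `plant_mask` from [segment_rosette()].
#' @return One-row tibble: `well`, `timestamp_h`, `ngrdi`, `gli`, `vari`,
#'   `n_pixels`, `n_undefined_px`, `empty`.
#' @export
plant_indices <- function(image, mask) {
  stopifnot(inherits(image, "plate_image"), inherits(mask, "plant_mask"))
  if (mask$green_area_px == 0) {
    return(tibble(well = mask$well, timestamp_h = mask$timestamp_h,
                  ngrdi = NA_real_, gli = NA_real_, vari = NA_real_,
                  n_pixels = 0L, n_undefined_px = 0L, empty = TRUE))
  }
  idx <- which(mask$mask, arr.ind = TRUE)
  ys <- idx[, 1] + mask$offset[2]
  xs <- idx[, 2] + mask$offset[1]
  px <- cbind(
    image$pixels[cbind(ys, xs, 1L)],
    image$pixels[cbind(ys, xs, 2L)],
    image$pixels[cbind(ys, xs, 3L)]
  )
  ind <- pixel_indices(px[, 1], px[, 2], px[, 3])
  tibble(
    well = mask$well, timestamp_h = mask$timestamp_h,
    ngrdi = mean(ind$ngrdi, na.rm = TRUE),
    gli = mean(ind$gli, na.rm = TRUE),
    vari = if (all(is.na(ind$vari))) NA_real_ else mean(ind$vari, na.rm = TRUE),
    n_pixels = nrow(ind),
    n_undefined_px = sum(is.na(ind$vari)),
    empty = FALSE
  )
}

#' Vegetation indices for every plant on a plate image
#'
#' Segments each well with [segment_rosette()] and computes
#' [plant_indices()]; typically run on the final imaging day.
#'
#' @inheritParams segment_rosette
#' @param wells Wells to process (default all).
#' @param treatments Optional [treatment_map()] joined on.
#' @return Tibble, one row per well (see [plant_indices()]).
#' @export
measure_plate_indices <- function(image, wells = NULL, threshold = 0.10,
                                  treatments = NULL) {
  wells <- wells %||% well_labels(image$layout)
  out <- map(wells, ~ plant_indices(image, segment_rosette(image, .x, threshold))) |>
    list_rbind()
  if (!is.null(treatments)) out <- left_join(out, as_tibble(treatments), by = "well")
  out
}

#' Plate-level index means
#'
#' Unweighted mean over plants of the per-plant index means (each plant
#' counts once regardless of its pixel count; this is not a pixel-pooled
#' mean). Plants with empty masks are excluded.
#'
#' @param records Tibble of per-plant records from [plant_indices()] /
#'   [measure_plate_indices()].
#' @return One-row tibble: `n_plants`, `ngrdi`, `gli`, `vari`.
#' @export
plate_indices <- function(records) {
  defined <- records |> filter(!.data$empty, is.finite(.data$gli))
  if (nrow(defined) == 0) {
    stop_phenoplate("no defined plant records on this plate", "summary_error")
  }
  defined |>
    summarise(
      n_plants = n(),
      ngrdi = mean(.data$ngrdi, na.rm = TRUE),
      gli = mean(.data$gli, na.rm = TRUE),
      vari = mean(.data$vari, na.rm = TRUE)
    )
}
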