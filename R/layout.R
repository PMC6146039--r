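#' Describe the well grid of a plate image
#'
#' A plate layout places a regular grid of wells on a scanned or top-view
#' plate image: the pixel position of the centre of well A1, the
#' centre-to-centre pitch, and the well radius (circular wells) or half-width
#' (square wells). All downstream modules address pixels through this grid,
#' so one layout object is shared by seed counting, rosette segmentation and
#' the synthetic generators.
#'
#' Wells are labelled row-letter + column-number with `A1` at the top left
#' and 1-based columns; image row 0 is the top of the image. Well regions
#' must be pairwise disjoint, which for a square grid means
#' `2 * radius_px <= pitch_px`.
#'
#' @param n_rows,n_cols Number of well rows and columns (8 x 12 for a
#'   96-well plate, 6 x 8 for a 48-well plate).
#' @param origin_px Numeric length-2, pixel `(x, y)` of the centre of well
#'   A1 (x = column direction, y = row direction, y grows downwards).
#' @param pitch_px Centre-to-centre well spacing in pixels.
#' @param radius_px Well radius (circle) or half-width (square) in pixels.
#' @param well_shape `"circle"` or `"square"`.
#' @param plate_id Free-text plate identifier carried into result tables.
#' @param image_size Optional `c(height, width)` of the plate image in
#'   pixels; defaults to a symmetric margin equal to `origin_px`.
#'
#' @return An object of class `plate_layout`: a list with the scalar fields
#'   above and `$wells`, a tibble with one row per well
#'   (`well`, `row`, `col`, `cx`, `cy`).
#' @examples
#' lay <- plate_layout_96()
#' lay$wells
#' @export
plate_layout <- function(n_rows, n_cols, origin_px, pitch_px, radius_px,
                         well_shape = c("circle", "square"),
                         plate_id = "plate", image_size = NULL) {
  well_shape <- arg_match(well_shape)
  stopifnot(n_rows >= 1, n_cols >= 1, length(origin_px) == 2,
            pitch_px > 0, radius_px > 0)
  if (n_rows > 26) stop_phenoplate("at most 26 well rows (A-Z) supported", "layout_error")
  if (2 * radius_px > pitch_px && (n_rows > 1 || n_cols > 1)) {
    stop_phenoplate("well regions overlap: 2 * radius_px exceeds pitch_px", "layout_error")
  }
  wells <- expand_grid(row = seq_len(n_rows), col = seq_len(n_cols)) |>
    mutate(
      well = paste0(LETTERS[.data$row], .data$col),
      cx = origin_px[1] + (.data$col - 1) * pitch_px,
      cy = origin_px[2] + (.data$row - 1) * pitch_px
    ) |>
    select("well", "row", "col", "cx", "cy")
  if (is.null(image_size)) {
    image_size <- c(
      origin_px[2] + (n_rows - 1) * pitch_px + origin_px[2],
      origin_px[1] + (n_cols - 1) * pitch_px + origin_px[1]
    )
  }
  image_size <- as.integer(round(image_size))
  pad <- if (well_shape == "circle") radius_px else radius_px * sqrt(2)
  if (any(wells$cx - pad < 0) || any(wells$cx + pad > image_size[2]) ||
      any(wells$cy - pad < 0) || any(wells$cy + pad > image_size[1])) {
    stop_phenoplate("some well regions fall outside the image", "layout_error")
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      well_shape = well_shape, origin_px = as.numeric(origin_px),
      pitch_px = as.numeric(pitch_px), radius_px = as.numeric(radius_px),
      plate_id = plate_id, image_size = image_size, wells = wells
    ),
    class = "plate_layout"
  )
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %s: %d x %d %s wells, pitch %.4g px, radius %.4g px, image %d x %d\n",
              x$plate_id, x$n_rows, x$n_cols, x$well_shape,
              x$pitch_px, x$radius_px, x$image_size[1], x$image_size[2]))
  invisible(x)
}

#' Default layouts for the two assay plate formats
#'
#' `plate_layout_96()` is the geometry used for synthetic 96-well seed
#' scans (8 x 12 circular wells) and `plate_layout_48()` for synthetic
#' 48-well rosette plates (6 x 8 wells, wide enough to hold a grown
#' rosette). Both are ordinary [plate_layout()] objects; real images just
#' need a layout with their own measured origin/pitch/radius.
#'
#' @param plate_id Plate identifier.
#' @return A `plate_layout`.
#' @export
plate_layout_96 <- function(plate_id = "plate96") {
  plate_layout(8, 12, origin_px = c(80, 80), pitch_px = 140, radius_px = 65,
               plate_id = plate_id)
}

#' @rdname plate_layout_96
#' @export
plate_layout_48 <- function(plate_id = "plate48") {
  plate_layout(6, 8, origin_px = c(55, 55), pitch_px = 90, radius_px = 40,
               plate_id = plate_id)
}

#' All well labels of a layout, in row-major order
#' @param layout A [plate_layout()].
#' @return Character vector like `c("A1", "A2", ...)`.
#' @export
well_labels <- function(layout) layout$wells$well

## Normalize a well label: "a01" -> "A1"; abort on labels outside the layout.
normalize_well <- function(well, layout = NULL) {
  well <- toupper(trimws(well))
  m <- stringr::str_match(well, "^([A-Z])0*([0-9]+)$")
  if (any(is.na(m[, 1]))) {
    stop_phenoplate(paste0("malformed well label(s): ",
                           paste(well[is.na(m[, 1])], collapse = ", ")),
                    "layout_error")
  }
  out <- paste0(m[, 2], as.integer(m[, 3]))
  if (!is.null(layout)) {
    bad <- setdiff(out, well_labels(layout))
    if (length(bad)) {
      stop_phenoplate(paste0("well(s) not in layout: ", paste(bad, collapse = ", ")),
                      "layout_error")
    }
  }
  out
}

#' Pixel region of one well
#'
#' Returns the bounding box and centre of a well's region. For circular
#' wells the region is the disk of `radius_px` around the centre; the box
#' is its enclosing square clipped to the image.
#'
#' @param layout A [plate_layout()].
#' @param well Single well label, e.g. `"B7"`.
#' @return A list with `well`, `cx`, `cy`, `r`, and integer pixel bounds
#'   `x0`, `x1`, `y0`, `y1` (inclusive, 1-based).
#' @export
well_region <- function(layout, well) {
  well <- normalize_well(well, layout)
  stopifnot(length(well) == 1)
  w <- layout$wells[layout$wells$well == well, ]
  r <- layout$radius_px
  list(
    well = well, cx = w$cx, cy = w$cy, r = r,
    x0 = max(1L, as.integer(floor(w$cx - r))),
    x1 = min(layout$image_size[2], as.integer(ceiling(w$cx + r))),
    y0 = max(1L, as.integer(floor(w$cy - r))),
    y1 = min(layout$image_size[1], as.integer(ceiling(w$cy + r)))
  )
}

## Logical mask of the well interior within the region's bounding box.
well_interior_mask <- function(layout, region) {
  ys <- region$y0:region$y1
  xs <- region$x0:region$x1
  if (layout$well_shape == "circle") {
    dy2 <- (ys - region$cy)^2
    dx2 <- (xs - region$cx)^2
    outer(dy2, dx2, "+") <= region$r^2
  } else {
    matrix(TRUE, length(ys), length(xs))
  }
}

#' Build or validate a treatment map
#'
#' A treatment map assigns every well of a layout exactly one treatment:
#' the priming compound (free text, `"none"` for untreated), its
#' concentration in mM, and the growth condition (`control`, `NaCl75`
#' or `NaCl150`, i.e. no salt, 75 mM or 150 mM NaCl).
#'
#' @param df Data frame with columns `well`, `compound`, `conc_mM`,
#'   `condition`.
#' @param layout Optional [plate_layout()]; when given, every layout well
#'   must be assigned exactly once.
#' @return A tibble with the four columns above, class `treatment_map`.
#' @export
treatment_map <- function(df, layout = NULL) {
  need <- c("well", "compound", "conc_mM", "condition")
  if (!all(need %in% names(df))) {
    stop_phenoplate(paste0("treatment map needs columns: ", paste(need, collapse = ", ")),
                    "treatment_error")
  }
  df <- as_tibble(df)[need]
  df$well <- normalize_well(df$well, layout)
  bad <- setdiff(unique(df$condition), conditions_enum())
  if (length(bad)) {
    stop_phenoplate(paste0("unknown condition(s): ", paste(bad, collapse = ", "),
                           " (allowed: ", paste(conditions_enum(), collapse = ", "), ")"),
                    "treatment_error")
  }
  if (anyDuplicated(df$well)) {
    stop_phenoplate("duplicate well assignment in treatment map", "treatment_error")
  }
  if (!is.null(layout)) {
    missing <- setdiff(well_labels(layout), df$well)
    if (length(missing)) {
      stop_phenoplate(paste0("unassigned well(s): ", paste(head(missing, 8), collapse = ", "),
                             if (length(missing) > 8) " ..."),
                      "treatment_error")
    }
  }
  df$conc_mM <- as.numeric(df$conc_mM)
  class(df) <- c("treatment_map", class(df))
  df
}

#' @rdname treatment_map
#' @export
conditions_enum <- function() c("control", "NaCl75", "NaCl150")

#' Read a plate layout and treatment map from a YAML config
#'
#' The config has a `plate` block (`id`, `rows`, `cols`, `shape`,
#' `origin_px`, `pitch_px`, `radius_px`, optional `image_size`) and an
#' optional `treatments` block mapping well labels to
#' `{compound, conc_mM, condition}`.
#'
#' @param path Path to the YAML file.
#' @return A list with `$layout` ([plate_layout()]) and `$treatments`
#'   ([treatment_map()] or `NULL`).
#' @export
read_layout_yaml <- function(path) {
  if (!file.exists(path)) {
    stop_phenoplate(paste0("layout config not found: ", path), "io_error")
  }
  cfg <- yaml::read_yaml(path)
  p <- cfg$plate
  if (is.null(p)) stop_phenoplate("layout config lacks a 'plate' block", "format_error")
  layout <- plate_layout(
    n_rows = p$rows, n_cols = p$cols,
    origin_px = as.numeric(unlist(p$origin_px)),
    pitch_px = p$pitch_px, radius_px = p$radius_px,
    well_shape = p$shape %||% "circle",
    plate_id = p$id %||% "plate",
    image_size = if (!is.null(p$image_size)) as.numeric(unlist(p$image_size))
  )
  treatments <- NULL
  if (!is.null(cfg$treatments)) {
    treatments <- imap(cfg$treatments, function(v, w) {
      tibble(well = w, compound = v$compound %||% "none",
             conc_mM = as.numeric(v$conc_mM %||% 0),
             condition = v$condition %||% "control")
    }) |>
      list_rbind() |>
      treatment_map(layout = layout)
  }
  list(layout = layout, treatments = treatments)
}

#' Write a layout (and optional treatment map) to YAML
#' @param layout A [plate_layout()].
#' @param path Output path.
#' @param treatments Optional [treatment_map()].
#' @return `path`, invisibly.
#' @export
write_layout_yaml <- function(layout, path, treatments = NULL) {
  cfg <- list(plate = list(
    id = layout$plate_id, rows = layout$n_rows, cols = layout$n_cols,
    shape = layout$well_shape, origin_px = layout$origin_px,
    pitch_px = layout$pitch_px, radius_px = layout$radius_px,
    image_size = as.integer(layout$image_size)
  ))
  if (!is.null(treatments)) {
    cfg$treatments <- setNames(
      pmap(treatments, function(well, compound, conc_mM, condition) {
        list(compound = compound, conc_mM = conc_mM, condition = condition)
      }),
      treatments$well
    )
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
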