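#' Construct a plate image record
#'
#' Bundles an RGB raster with its acquisition time and the plate layout
#' describing where the wells sit in the raster. All channel values must be
#' normalized to `[0, 1]`; readers do this on load so every downstream
#' computation (thresholds, vegetation indices) is independent of the input
#' bit depth.
#'
#' @param pixels Numeric array `height x width x 3`, values in `[0, 1]`.
#' @param layout A [plate_layout()] whose `image_size` matches `pixels`.
#' @param timestamp_h Acquisition time in hours on the experiment clock.
#' @param source_path Optional provenance string.
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, layout, timestamp_h = 0, source_path = NA_character_) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop_phenoplate("pixels must be a height x width x 3 RGB array", "format_error")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop_phenoplate("channel values must be finite and within [0, 1]", "format_error")
  }
  if (!is.finite(timestamp_h)) {
    stop_phenoplate("timestamp_h must be finite", "format_error")
  }
  if (!all(dim(pixels)[1:2] == layout$image_size)) {
    stop_phenoplate(sprintf(
      "image is %d x %d but layout expects %d x %d",
      dim(pixels)[1], dim(pixels)[2], layout$image_size[1], layout$image_size[2]),
      "layout_error")
  }
  structure(
    list(pixels = pixels, timestamp_h = as.numeric(timestamp_h),
         layout = layout, source_path = source_path),
    class = "plate_image"
  )
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("<plate_image> %d x %d px, t = %.4g h, plate %s\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$timestamp_h,
              x$layout$plate_id))
  invisible(x)
}

#' Read an RGB plate scan from PNG or TIFF
#'
#' 8-bit and 16-bit inputs both map linearly onto `[0, 1]` (the underlying
#' readers divide by the sample maximum). Grayscale images are rejected:
#' the seed and rosette segmentation rules need all three colour channels.
#' An alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams plate_image
#' @return A [plate_image()].
#' @export
read_plate_image <- function(path, layout, timestamp_h = 0) {
  if (!file.exists(path)) {
    stop_phenoplate(paste0("image file not found: ", path), "io_error")
  }
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_phenoplate(paste0("unsupported image format '.", ext, "': ", path), "io_error")
  )
  if (length(dim(px)) < 3 || dim(px)[3] < 3) {
    stop_phenoplate(paste0("grayscale image not supported (RGB required): ", path),
                    "format_error")
  }
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  plate_image(px, layout, timestamp_h, source_path = path)
}

#' Write a plate image to PNG
#' @param image A [plate_image()].
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_plate_image <- function(image, path) {
  stopifnot(inherits(image, "plate_image"))
  png::writePNG(image$pixels, path)
  invisible(path)
}

## Crop the pixels of one well; returns list(pixels, inside, region) where
## `inside` masks the well interior within the crop.
crop_well <- function(image, well) {
  region <- well_region(image$layout, well)
  px <- image$pixels[region$y0:region$y1, region$x0:region$x1, , drop = FALSE]
  list(pixels = px, inside = well_interior_mask(image$layout, region),
       region = region)
}

#' Read a dual-wavelength absorbance plate from CSV
#'
#' Supports two dialects written by plate-reader exports:
#' \describe{
#'   \item{`long`}{columns `well,wavelength,value`, wavelengths 570 and 690,
#'     one row per well per wavelength.}
#'   \item{`grid8x12`}{two blocks, each introduced by a line
#'     `wavelength,<nm>` followed by a header row `,1,2,...,12` and 8 rows
#'     `A,...` to `H,...`. Optional leading `plate_id,<id>` and
#'     `timepoint_h,<h>` lines.}
#' }
#' With `dialect = "auto"` (default) the format is sniffed from the header.
#' Well labels are normalized (`a01` -> `A1`); both wavelengths must cover
#' the same well set.
#'
#' @param path CSV path.
#' @param dialect `"auto"`, `"grid8x12"` or `"long"`.
#' @param plate_id,timepoint_h Metadata overrides; the grid dialect can
#'   carry both in-file.
#' @return A tibble of class `absorbance_plate` with columns `well`,
#'   `a570`, `a690` and attributes `plate_id`, `timepoint_h`.
#' @export
read_absorbance_csv <- function(path, dialect = c("auto", "grid8x12", "long"),
                                plate_id = NULL, timepoint_h = NULL) {
  dialect <- arg_match(dialect)
  if (!file.exists(path)) {
    stop_phenoplate(paste0("absorbance file not found: ", path), "io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_phenoplate(paste0("empty absorbance file: ", path), "format_error")
  if (dialect == "auto") {
    dialect <- if (grepl("^\\s*well\\s*,", lines[1], ignore.case = TRUE)) "long" else "grid8x12"
  }
  if (dialect == "long") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("well", "wavelength", "value")
    if (!all(need %in% names(df))) {
      stop_phenoplate("long dialect needs columns well, wavelength, value", "format_error")
    }
    df$well <- normalize_well(df$well)
    if (anyDuplicated(df[c("well", "wavelength")])) {
      stop_phenoplate("duplicate well/wavelength rows in long absorbance CSV",
                      "format_error")
    }
    wide <- df |>
      mutate(wavelength = paste0("a", .data$wavelength)) |>
      pivot_wider(id_cols = "well", names_from = "wavelength", values_from = "value")
    for (w in c("a570", "a690")) {
      if (!w %in% names(wide) || anyNA(wide[[w]])) {
        stop_phenoplate(paste0("missing ", sub("a", "", w),
                               " nm readings for some wells"), "format_error")
      }
    }
    out <- wide[c("well", "a570", "a690")]
  } else {
    fields <- strsplit(lines, ",")
    key <- tolower(vapply(fields, function(f) trimws(f[1]), ""))
    meta_id <- which(key == "plate_id")
    meta_tp <- which(key == "timepoint_h")
    if (length(meta_id) && is.null(plate_id)) plate_id <- trimws(fields[[meta_id[1]]][2])
    if (length(meta_tp) && is.null(timepoint_h)) {
      timepoint_h <- as.numeric(fields[[meta_tp[1]]][2])
    }
    starts <- which(key == "wavelength")
    if (length(starts) < 2) {
      stop_phenoplate("grid dialect needs a 'wavelength' block for 570 and 690 nm",
                      "format_error")
    }
    blocks <- list()
    for (s in starts) {
      nm <- as.integer(fields[[s]][2])
      block_rows <- fields[(s + 2):(s + 9)]  # skip the ,1..12 header row
      vals <- lapply(block_rows, function(f) as.numeric(f[2:13]))
      rows <- vapply(block_rows, function(f) toupper(trimws(f[1])), "")
      if (!identical(rows, LETTERS[1:8]) || anyNA(unlist(vals))) {
        stop_phenoplate("malformed 8 x 12 grid block", "format_error")
      }
      blocks[[as.character(nm)]] <- tibble(
        well = paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8)),
        value = unlist(vals)
      )
    }
    if (!all(c("570", "690") %in% names(blocks))) {
      stop_phenoplate("grid dialect must contain both 570 and 690 nm blocks",
                      "format_error")
    }
    out <- tibble(well = blocks[["570"]]$well,
                  a570 = blocks[["570"]]$value,
                  a690 = blocks[["690"]]$value)
  }
  if (any(!is.finite(out$a570)) || any(!is.finite(out$a690))) {
    stop_phenoplate("non-finite absorbance values", "format_error")
  }
  absorbance_plate(out, plate_id = plate_id %||% "plate",
                   timepoint_h = timepoint_h %||% NA_real_)
}

#' @rdname read_absorbance_csv
#' @param df Tibble with columns `well`, `a570`, `a690`.
#' @export
absorbance_plate <- function(df, plate_id = "plate", timepoint_h = NA_real_) {
  need <- c("well", "a570", "a690")
  if (!all(need %in% names(df))) {
    stop_phenoplate("absorbance plate needs columns well, a570, a690", "format_error")
  }
  df <- as_tibble(df)[need]
  df$well <- normalize_well(df$well)
  attr(df, "plate_id") <- plate_id
  attr(df, "timepoint_h") <- timepoint_h
  class(df) <- c("absorbance_plate", class(df))
  df
}

#' Write an absorbance plate to CSV
#'
#' @param plate An [absorbance_plate()].
#' @param path Output path.
#' @param dialect `"long"` (default) or `"grid8x12"` (requires a full
#'   96-well plate).
#' @return `path`, invisibly.
#' @export
write_absorbance_csv <- function(plate, path, dialect = c("long", "grid8x12")) {
  dialect <- arg_match(dialect)
  if (dialect == "long") {
    long <- plate |>
      as_tibble() |>
      pivot_longer(c("a570", "a690"), names_to = "wavelength", values_to = "value") |>
      mutate(wavelength = as.integer(sub("a", "", .data$wavelength)))
    readr::write_csv(long, path)
  } else {
    if (nrow(plate) != 96 || !setequal(plate$well, well_labels(plate_layout_96()))) {
      stop_phenoplate("grid8x12 dialect requires a complete 96-well plate", "format_error")
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("plate_id,", attr(plate, "plate_id")), con)
    tp <- attr(plate, "timepoint_h")
    if (!is.na(tp)) writeLines(paste0("timepoint_h,", format(tp, digits = 15)), con)
    ord <- match(paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8)), plate$well)
    for (w in c("a570", "a690")) {
      writeLines(paste0("wavelength,", sub("a", "", w)), con)
      writeLines(paste0(",", paste(1:12, collapse = ",")), con)
      vals <- matrix(plate[[w]][ord], nrow = 8, byrow = TRUE)
      for (i in 1:8) {
        writeLines(paste(c(LETTERS[i], format(vals[i, ], digits = 15, trim = TRUE)),
                         collapse = ","), con)
      }
    }
  }
  invisible(path)
}

#' Write a result table to CSV
#'
#' Plain CSV with a header and stable column order; doubles are serialized
#' at full precision so a write/read round trip preserves values to
#' better than 1e-9.
#'
#' @param records Non-empty data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop_phenoplate("refusing to write an empty result table", "format_error")
  }
  readr::write_csv(as_tibble(records), path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the inputs, parameters, seeds and package version of a pipeline
#' run, so a run can be reproduced from its output directory alone.
#'
#' @param path Output `.json` path.
#' @param inputs,params Named lists describing input files and stage
#'   parameters.
#' @param seed Integer RNG seed used by the run (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, inputs = list(), params = list(), seed = NULL) {
  manifest <- list(
    software = "phenoplate",
    version = as.character(utils::packageVersion("phenoplate")),
    schema_version = "1",
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = inputs,
    params = params
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
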