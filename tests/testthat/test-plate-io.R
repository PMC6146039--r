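test_that("plate layout builds a labelled, disjoint well grid", {
  lay <- plate_layout(8, 12, origin_px = c(40, 40), pitch_px = 60,
                      radius_px = 26)
  expect_equal(nrow(lay$wells), 96)
  expect_equal(lay$wells$well[1], "A1")
  expect_equal(lay$wells$well[13], "B1")
  expect_equal(lay$wells$cx[2] - lay$wells$cx[1], 60)
  # A1 is top-left: smallest cx and cy
  expect_equal(lay$wells$cx[which.min(lay$wells$cx + lay$wells$cy)],
               min(lay$wells$cx))
  # overlapping wells rejected
  expect_error(plate_layout(2, 2, c(30, 30), pitch_px = 40, radius_px = 21),
               class = "layout_error")
  # wells outside the image rejected
  expect_error(plate_layout(2, 2, c(10, 10), pitch_px = 60, radius_px = 26),
               class = "layout_error")
})

test_that("well labels normalize and bad labels fail", {
  lay <- mini_layout()
  expect_equal(phenoplate:::normalize_well(c("a01", "B3")), c("A1", "B3"))
  expect_error(phenoplate:::normalize_well("11A"), class = "layout_error")
  expect_error(phenoplate:::normalize_well("Z9", lay), class = "layout_error")
})

test_that("every well region lies fully inside the image", {
  for (lay in list(plate_layout_96(), plate_layout_48(), mini_layout())) {
    for (w in well_labels(lay)) {
      reg <- well_region(lay, w)
      expect_gte(reg$x0, 1)
      expect_gte(reg$y0, 1)
      expect_lte(reg$x1, lay$image_size[2])
      expect_lte(reg$y1, lay$image_size[1])
    }
  }
})

test_that("plate images round-trip through PNG and TIFF at 8 and 16 bit", {
  lay <- mini_layout()
  img <- flat_image(lay, c(0.2, 0.8, 0.4))
  img$pixels[1, 1, ] <- c(0, 1, 0)
  for (ext in c("png", "tiff")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    if (ext == "png") {
      png::writePNG(img$pixels, path)
    } else {
      tiff::writeTIFF(img$pixels, path, bits.per.sample = 16)
    }
    back <- read_plate_image(path, lay, timestamp_h = 3)
    expect_equal(back$timestamp_h, 3)
    expect_true(all(back$pixels >= 0 & back$pixels <= 1))
    # 8-bit (0,255,0) and 16-bit (0,65535,0) both map to (0,1,0)
    expect_equal(back$pixels[1, 1, ], c(0, 1, 0))
    expect_lt(max(abs(back$pixels - img$pixels)), 1 / 255)
  }
})

test_that("grayscale and missing images are rejected with the path named", {
  lay <- mini_layout()
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 20, 20), path)
  err <- expect_error(read_plate_image(path, lay), class = "format_error")
  expect_match(conditionMessage(err), basename(path), fixed = TRUE)
  expect_error(read_plate_image("no/such/file.png", lay), class = "io_error")
})

test_that("absorbance CSVs round-trip in both dialects", {
  set.seed(1)
  wells96 <- well_labels(plate_layout_96())
  plate <- absorbance_plate(
    tibble::tibble(well = wells96, a570 = runif(96, 0.1, 1),
                   a690 = runif(96, 0, 0.2)),
    plate_id = "RT", timepoint_h = 24
  )
  for (dialect in c("long", "grid8x12")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_absorbance_csv(plate, path, dialect = dialect)
    back <- read_absorbance_csv(path)  # auto-detected
    m <- match(plate$well, back$well)
    expect_lt(max(abs(back$a570[m] - plate$a570)), 1e-9)
    expect_lt(max(abs(back$a690[m] - plate$a690)), 1e-9)
  }
  # grid dialect carries its metadata
  path <- withr::local_tempfile(fileext = ".csv")
  write_absorbance_csv(plate, path, dialect = "grid8x12")
  back <- read_absorbance_csv(path)
  expect_equal(attr(back, "plate_id"), "RT")
  expect_equal(attr(back, "timepoint_h"), 24)
})

test_that("long dialect parses explicit rows and rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,wavelength,value", "A1,570,0.9", "A1,690,0.2"), path)
  plate <- read_absorbance_csv(path)
  expect_equal(plate$a570[plate$well == "A1"], 0.9)
  expect_equal(plate$a690[plate$well == "A1"], 0.2)
  writeLines(c("well,wavelength,value", "A1,570,0.9", "A1,570,0.8",
               "A1,690,0.2"), path)
  expect_error(read_absorbance_csv(path), class = "format_error")
  # missing wavelength block
  writeLines(c("well,wavelength,value", "A1,570,0.9"), path)
  expect_error(read_absorbance_csv(path), class = "format_error")
})

test_that("result tables round-trip and empty tables are refused", {
  df <- tibble::tibble(x = c(1.23456789e-5, pi), label = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_table(df, path)
  lines <- readLines(path)
  expect_length(lines, 3)  # header + 2 rows
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_lt(max(abs(back$x - df$x)), 1e-9)
  expect_error(write_results_table(df[0, ], path), class = "format_error")
  expect_false(file.size(path) == 0)
})

test_that("layout YAML round-trips with treatments", {
  lay <- mini_layout()
  tm <- treatment_map(
    tibble::tibble(well = well_labels(lay),
                   compound = c("none", "Put", "Put", "Spd", "Pro", "none"),
                   conc_mM = c(0, 0.1, 1, 0.01, 1, 0),
                   condition = c("control", "control", "NaCl75", "NaCl150",
                                 "control", "NaCl75")),
    lay
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_layout_yaml(lay, path, treatments = tm)
  back <- read_layout_yaml(path)
  expect_equal(back$layout$pitch_px, lay$pitch_px)
  expect_equal(back$layout$wells, lay$wells)
  expect_equal(as.data.frame(back$treatments[order(back$treatments$well), ]),
               as.data.frame(tm[order(tm$well), ]))
})

test_that("treatment maps validate conditions and coverage", {
  lay <- mini_layout()
  df <- tibble::tibble(well = well_labels(lay), compound = "none",
                       conc_mM = 0, condition = "control")
  expect_s3_class(treatment_map(df, lay), "treatment_map")
  expect_error(treatment_map(dplyr::mutate(df, condition = "NaCl999"), lay),
               class = "treatment_error")
  expect_error(treatment_map(df[-1, ], lay), class = "treatment_error")
  expect_error(treatment_map(rbind(df, df[1, ]), lay),
               class = "treatment_error")
})
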