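test_that("identical seeds give bit-identical artifacts", {
  lay <- mini_layout(1, 2)
  g1 <- generate_seed_scan(seed_scan_scenario(rng_seed = 9), lay)
  g2 <- generate_seed_scan(seed_scan_scenario(rng_seed = 9), lay)
  expect_identical(g1$image$pixels, g2$image$pixels)
  expect_identical(g1$manifest, g2$manifest)
  g3 <- generate_seed_scan(seed_scan_scenario(rng_seed = 10), lay)
  expect_false(identical(g1$manifest$n_seeds, g3$manifest$n_seeds))

  counts <- tibble::tibble(well = c("A1", "A2"), n_seeds = c(20L, 25L))
  m1 <- generate_mtt_table(mtt_scenario(rng_seed = 4), counts)
  m2 <- generate_mtt_table(mtt_scenario(rng_seed = 4), counts)
  expect_identical(m1$plate$a570, m2$plate$a570)

  lay48 <- mini_layout_48()
  w1 <- generate_growth_images(growth_scenario(rng_seed = 2, n_days = 2), lay48)
  w2 <- generate_growth_images(growth_scenario(rng_seed = 2, n_days = 2), lay48)
  expect_identical(w1$images[[3]]$pixels, w2$images[[3]]$pixels)
  expect_identical(w1$manifest, w2$manifest)
})

test_that("a zero-seed scenario renders a blank plate", {
  lay <- mini_layout(1, 2)
  g <- generate_seed_scan(seed_scan_scenario(seeds_per_well_mean = 0,
                                             seeds_per_well_sd = 0,
                                             rng_seed = 1), lay)
  expect_true(all(g$manifest$n_seeds == 0))
  counts <- count_plate_seeds(g$image, avg_seed_area_px = 79)
  expect_true(all(counts$seed_count == 0))
})

test_that("without clusters every rendered object is convex", {
  lay <- mini_layout(1, 2)
  g <- generate_seed_scan(seed_scan_scenario(cluster_fraction = 0,
                                             rng_seed = 3), lay)
  for (w in well_labels(lay)) {
    obj <- measure_objects(segment_seeds(g$image, w, avg_seed_area_px = 79))
    expect_true(all(obj$solidity >= 0.9))
    expect_equal(nrow(obj), g$manifest$n_seeds[g$manifest$well == w])
  }
})

test_that("drawn counts follow the dispensing distribution", {
  g <- generate_seed_scan(seed_scan_scenario(rng_seed = 17))
  expect_equal(nrow(g$manifest), 96)
  expect_lt(abs(mean(g$manifest$n_seeds) - 21), 1.5)
  expect_lt(abs(sd(g$manifest$n_seeds) - 5.4), 2)
})

test_that("noise-free MTT wells reproduce the exact arithmetic", {
  sc <- mtt_scenario(sd_seed = 0, reader_noise_sd = 0, well_effect_cv = 0,
                     mu_nongerm = 0, sd_nongerm = 0)
  g <- generate_mtt_table(sc, tibble::tibble(well = "A1", n_seeds = 21L))
  expect_equal(g$manifest$net_abs, 21 * 0.019)  # 0.399
  # manifest signal reconstructs the plate exactly
  expect_equal(g$plate$a570 - g$plate$a690, g$manifest$true_signal)
})

test_that("non-germinating seeds contribute only trace signal", {
  set.seed(1)
  counts <- tibble::tibble(well = paste0("A", 1:12), n_seeds = 20L)
  g <- generate_mtt_table(mtt_scenario(germination_fraction = 0,
                                       reader_noise_sd = 0, rng_seed = 2),
                          counts)
  expect_true(all(g$manifest$n_germinated == 0))
  expect_lt(max(g$manifest$net_abs / 20), 0.0025)  # << 0.019
})

test_that("the default cohort lands near the published net absorbance", {
  set.seed(3)
  counts <- tibble::tibble(well = well_labels(plate_layout_96()),
                           n_seeds = as.integer(pmax(0, round(rnorm(96, 21, 5.4)))))
  g <- generate_mtt_table(mtt_scenario(rng_seed = 5), counts)
  expect_lt(abs(mean(g$manifest$net_abs) - 0.399), 0.1 * 0.399)
})

test_that("zero growth renders identical frames and zero pipeline RGR", {
  lay <- mini_layout_48()
  g <- generate_growth_images(
    growth_scenario(r_day = 0, r_night = 0, a0_cv = 0, noise_sd = 0,
                    n_days = 2, rng_seed = 6),
    lay
  )
  expect_identical(g$images[[1]]$pixels, g$images[[2]]$pixels)
  areas <- measure_plate_growth(g$images)
  expect_equal(unique(rgr(build_timeseries(areas))$rgr), 0)
})

test_that("rendered areas equal the rounded true areas exactly", {
  lay <- mini_layout_48()
  g <- generate_growth_images(
    growth_scenario(rng_seed = 7, noise_sd = 0, n_days = 3), lay)
  expect_equal(g$manifest$area_px, as.integer(round(g$manifest$true_area)))
})

test_that("stress suppression halves measured growth as planted", {
  lay <- mini_layout_48(2, 3)
  mk <- function(cond) {
    tm <- treatment_map(tibble::tibble(well = well_labels(lay),
                                       compound = "none", conc_mM = 0,
                                       condition = cond), lay)
    g <- generate_growth_images(
      growth_scenario(rng_seed = 8, a0_cv = 0,
                      stress_suppression = c(NaCl75 = 0.7, NaCl150 = 0.5),
                      n_days = 4),
      lay, treatments = tm)
    areas <- measure_plate_growth(g$images)
    summarize_growth(build_timeseries(areas, treatments = tm))
  }
  ctl <- mk("control"); stress <- mk("NaCl150")
  # suppression acts on log-growth: measured log-area gain ratio ~ 0.5
  gain <- function(s) mean(log(s$final_area_px) - log(s$t0_area_px))
  expect_lt(abs(gain(stress) / gain(ctl) - 0.5), 0.05)
})

test_that("a rosette larger than its well aborts generation", {
  lay <- mini_layout_48()
  expect_error(
    generate_growth_images(growth_scenario(a0_px = 40000, rng_seed = 1,
                                           n_days = 2), lay),
    class = "scenario_error"
  )
})

test_that("oversized seeds abort scan generation", {
  lay <- mini_layout(1, 1)
  expect_error(
    generate_seed_scan(seed_scan_scenario(seed_axis_a_px = 40, rng_seed = 1),
                       lay),
    class = "scenario_error"
  )
})

test_that("generated artifacts are accepted by the package readers", {
  dir <- withr::local_tempdir()
  lay <- mini_layout(1, 2)
  g <- generate_seed_scan(seed_scan_scenario(rng_seed = 2), lay)
  p <- file.path(dir, "scan.png")
  expect_no_warning(write_plate_image(g$image, p))
  back <- read_plate_image(p, lay)
  expect_equal(dim(back$pixels), dim(g$image$pixels))

  counts <- g$manifest[c("well", "n_seeds")]
  m <- generate_mtt_table(mtt_scenario(rng_seed = 3), counts)
  pcsv <- file.path(dir, "mtt.csv")
  write_absorbance_csv(m$plate, pcsv)
  expect_no_warning(read_absorbance_csv(pcsv))
})
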