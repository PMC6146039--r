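test_that("a uniform background well yields an all-false mask", {
  lay <- mini_layout()
  img <- flat_image(lay, c(0.9, 0.88, 0.86))
  mask <- segment_seeds(img, "A1")
  expect_false(any(mask))
  expect_equal(nrow(measure_objects(mask)), 0)
})

test_that("three disjoint dark ellipses segment into three components", {
  lay <- mini_layout()
  img <- flat_image(lay, c(0.9, 0.88, 0.86))
  reg <- well_region(lay, "A1")
  img <- paint_ellipse(img, reg$cx - 30, reg$cy, 6, 4, 0.3)
  img <- paint_ellipse(img, reg$cx + 30, reg$cy - 20, 6, 4, 1.2)
  img <- paint_ellipse(img, reg$cx + 10, reg$cy + 30, 6, 4, 2.0)
  mask <- segment_seeds(img, "A1")
  obj <- measure_objects(mask)
  expect_equal(nrow(obj), 3)
  expect_true(all(obj$solidity > 0.9))
})

test_that("objects touching the well boundary are retained", {
  lay <- mini_layout()
  img <- flat_image(lay, c(0.9, 0.88, 0.86))
  reg <- well_region(lay, "B2")
  # ellipse centred just inside the rim so it is clipped by the interior
  img <- paint_ellipse(img, reg$cx + reg$r - 3, reg$cy, 6, 4, 0)
  obj <- measure_objects(segment_seeds(img, "B2"))
  expect_equal(nrow(obj), 1)
})

test_that("solidity matches the brute-force convex hull on known shapes", {
  # filled disk: convex, solidity near 1
  m <- disk_mask(30, 30, 15, 15, 10)
  obj <- measure_objects(m)
  expect_gte(obj$solidity, 0.95)
  # two-lobed dumbbell (overlapping disks 1.6 r apart): below a disk
  m2 <- disk_mask(40, 60, 20, 20, 10) | disk_mask(40, 60, 20, 36, 10)
  obj2 <- measure_objects(m2)
  expect_equal(nrow(obj2), 1)
  expect_lt(obj2$solidity, obj$solidity)
  # convex area agrees with the brute-force oracle
  expect_equal(obj2$convex_area_px, brute_convex_area(m2))
  expect_equal(obj$convex_area_px, brute_convex_area(m))
  # solidity is area / convex area, in (0, 1]
  expect_equal(obj2$solidity, obj2$area_px / obj2$convex_area_px)
  expect_lte(obj$solidity, 1)
})

test_that("connected components use 8-connectivity", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[4, 4] <- TRUE  # diagonal chain
  expect_equal(nrow(measure_objects(m)), 1)
})

test_that("count_seeds applies the solidity rule and cluster rounding", {
  singles <- tibble::tibble(object_id = 1:5, area_px = 120L,
                            convex_area_px = 125L, solidity = 0.96,
                            centroid_x = 1:5, centroid_y = 1:5)
  det <- count_seeds(singles, avg_seed_area_px = 120)
  expect_equal(attr(det, "seed_count"), 5)
  expect_false(any(det$is_cluster))

  cluster <- tibble::tibble(object_id = 1L, area_px = 252L,  # 2.1 x avg
                            convex_area_px = 360L, solidity = 0.7,
                            centroid_x = 0, centroid_y = 0)
  det2 <- count_seeds(cluster, avg_seed_area_px = 120)
  expect_equal(det2$estimated_seeds, 2L)
  # a flagged cluster can never count fewer than 2 seeds
  small_cluster <- dplyr::mutate(cluster, area_px = 100L)
  expect_equal(count_seeds(small_cluster, 120)$estimated_seeds, 2L)
  # rounding is half away from zero: 2.5 x avg -> 3
  mid <- dplyr::mutate(cluster, area_px = 300L)
  expect_equal(count_seeds(mid, 120)$estimated_seeds, 3L)
  expect_error(count_seeds(singles, avg_seed_area_px = 0),
               class = "parameter_error")
})

test_that("average seed area is the median of high-solidity objects", {
  obj <- tibble::tibble(area_px = c(100, 110, 120, 130, 140, 500, 480),
                        solidity = c(rep(0.95, 5), 0.6, 0.5))
  expect_equal(estimate_avg_seed_area(obj, min_n = 5), 120)
  expect_error(estimate_avg_seed_area(obj, min_n = 10),
               class = "estimation_error")
})

test_that("seed count is invariant to rotation and mirroring of the well", {
  set.seed(21)
  lay1 <- plate_layout(1, 1, origin_px = c(80, 80), pitch_px = 140,
                       radius_px = 65, plate_id = "one")
  gen <- generate_seed_scan(seed_scan_scenario(rng_seed = 21), lay1)
  mask <- segment_seeds(gen$image, "A1")
  count0 <- attr(count_seeds(measure_objects(mask), 79), "seed_count")
  rot90 <- t(mask)[ncol(mask):1, ]       # 90 degree rotation
  mirror <- mask[, ncol(mask):1]
  for (m in list(rot90, mirror)) {
    attr(m, "offset") <- c(0, 0)
    expect_equal(attr(count_seeds(measure_objects(m), 79), "seed_count"),
                 count0)
  }
})

test_that("adding one disjoint convex seed raises the count by exactly one", {
  lay <- mini_layout()
  img <- flat_image(lay, c(0.9, 0.88, 0.86))
  reg <- well_region(lay, "A2")
  img <- paint_ellipse(img, reg$cx - 25, reg$cy - 25, 6, 4.2, 0.4)
  img <- paint_ellipse(img, reg$cx + 25, reg$cy, 6, 4.2, 1.4)
  base <- attr(count_seeds(measure_objects(segment_seeds(img, "A2")), 79),
               "seed_count")
  img2 <- paint_ellipse(img, reg$cx - 10, reg$cy + 30, 6, 4.2, 2.2)
  more <- attr(count_seeds(measure_objects(segment_seeds(img2, "A2")), 79),
               "seed_count")
  expect_equal(more, base + 1)
})

test_that("counts are recovered on a small synthetic plate", {
  lay <- mini_layout(2, 3)
  gen <- generate_seed_scan(seed_scan_scenario(rng_seed = 5), lay)
  counts <- count_plate_seeds(gen$image)
  cmp <- dplyr::left_join(counts, gen$manifest, by = "well")
  expect_lte(mean(abs(cmp$seed_count - cmp$n_seeds)), 1)
  expect_equal(counts$plate_id, rep("mini", 6))
})
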