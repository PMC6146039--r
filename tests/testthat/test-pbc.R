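test_that("trait log2 ratios obey the basic identities", {
  expect_equal(trait_log2_ratio(5, 5), 0)
  expect_equal(trait_log2_ratio(4, 2), 1)
  expect_equal(trait_log2_ratio(2, 4), -1)
  # a 22 % greenness gain is ~0.287 log2 units
  expect_equal(trait_log2_ratio(1.22, 1), 0.287, tolerance = 0.002)
  # antisymmetry
  expect_equal(trait_log2_ratio(3, 7), -trait_log2_ratio(7, 3))
  err <- expect_error(trait_log2_ratio(0, 1, what = "growth (Put 1 mM)"),
                      class = "domain_error")
  expect_match(conditionMessage(err), "growth")
})

neutral_effects <- function() {
  tidyr::expand_grid(compound = c("Put", "Pro"), conc_mM = c(0.1, 1),
                     condition = conditions_enum()) |>
    dplyr::mutate(germination_x = 1, establishment_x = 1, growth_x = 1,
                  color_x = 1)
}

test_that("PBC of a neutral table is zero and labels neutral", {
  tt <- generate_trait_table(neutral_effects())
  pbc <- compute_pbc(tt$traits)
  expect_equal(pbc$pbc, rep(0, nrow(pbc)))
  expect_equal(unique(pbc$label), "neutral")
})

test_that("doubling all four traits under control gives PBC 4", {
  eff <- neutral_effects() |>
    dplyr::mutate(across(dplyr::ends_with("_x"),
                         ~ ifelse(condition == "control", 2, .x)))
  pbc <- compute_pbc(generate_trait_table(eff)$traits)
  ctl <- pbc[pbc$condition == "control", ]
  expect_equal(ctl$pbc, rep(4, nrow(ctl)))
  expect_equal(unique(ctl$label), "biostimulant")
  # stress conditions sum three traits (no establishment)
  stress <- pbc[pbc$condition != "control", ]
  expect_true(all(is.na(stress$log2_establishment)))
})

test_that("a planted growth effect appears alone in every condition", {
  eff <- neutral_effects() |> dplyr::mutate(growth_x = 1.5)
  pbc <- compute_pbc(generate_trait_table(eff)$traits)
  expect_equal(pbc$pbc, rep(log2(1.5), nrow(pbc)), tolerance = 1e-12)
})

test_that("PBC equals the sum of log2 multipliers for random tables", {
  set.seed(60)
  eff <- tidyr::expand_grid(compound = c("Put", "Spd", "Spm", "Pro"),
                            conc_mM = c(0.001, 0.01, 0.1, 1),
                            condition = conditions_enum()) |>
    dplyr::mutate(germination_x = exp(rnorm(dplyr::n(), 0, 0.4)),
                  establishment_x = exp(rnorm(dplyr::n(), 0, 0.4)),
                  growth_x = exp(rnorm(dplyr::n(), 0, 0.4)),
                  color_x = exp(rnorm(dplyr::n(), 0, 0.4)))
  tt <- generate_trait_table(eff)
  pbc <- compute_pbc(tt$traits)
  cmp <- dplyr::inner_join(pbc, tt$expected,
                           by = c("compound", "conc_mM", "condition"),
                           suffix = c("", ".exp"))
  expect_equal(nrow(cmp), 48)
  expect_lt(max(abs(cmp$pbc - cmp$pbc.exp)), 1e-12)
})

test_that("PBC is antisymmetric and monotone in single traits", {
  eff <- neutral_effects() |>
    dplyr::mutate(growth_x = 2, color_x = 1.3)
  tt <- generate_trait_table(eff)$traits
  pbc <- compute_pbc(tt)
  # swapping variant and control values negates every ratio and the sum:
  # the inverse-multiplier table is exactly that swap
  inv <- eff |> dplyr::mutate(growth_x = 1 / 2, color_x = 1 / 1.3)
  pbc_inv <- compute_pbc(generate_trait_table(inv)$traits)
  expect_equal(pbc_inv$pbc, -pbc$pbc, tolerance = 1e-12)
  # monotonicity: raising one trait of one variant raises its pbc strictly
  bumped <- tt
  i <- which(tt$compound != "none")[1]
  bumped$color[i] <- bumped$color[i] * 1.1
  key <- tt[i, c("compound", "conc_mM", "condition")]
  pick <- function(p) p$pbc[p$compound == key$compound &
                              p$conc_mM == key$conc_mM &
                              p$condition == key$condition]
  expect_gt(pick(compute_pbc(bumped)), pick(pbc))
})

test_that("missing matched controls raise a pairing error", {
  tt <- generate_trait_table(neutral_effects())$traits
  expect_error(compute_pbc(tt[tt$compound != "none", ]),
               class = "pairing_error")
})

test_that("mode classification follows the decision rules", {
  mk <- function(pbc_ctl, pbc_75, pbc_150) {
    tibble::tibble(compound = "X", conc_mM = 1,
                   condition = c("control", "NaCl75", "NaCl150"),
                   pbc = c(pbc_ctl, pbc_75, pbc_150))
  }
  expect_equal(classify_mode(mk(2.0, 2.5, 3.0))$mode, "combined")
  expect_equal(classify_mode(mk(0.0, 0.05, 1.2))$mode, "stress_alleviator")
  expect_equal(classify_mode(mk(1.5, 0.0, -0.5))$mode, "growth_promotor")
  expect_equal(classify_mode(mk(-1.0, 0.0, -0.3))$mode, "growth_inhibitor")
  expect_equal(classify_mode(mk(0.05, -0.05, 0.0))$mode, "none")
  # missing control record
  expect_error(classify_mode(mk(1, 1, 1)[-1, ]),
               class = "classification_error")
})

test_that("chart exports have the documented shape and round-trip", {
  eff <- default_screen_effects()
  tt <- generate_trait_table(eff)
  pbc <- compute_pbc(tt$traits)
  dir <- withr::local_tempdir()
  files <- export_charts(pbc, file.path(dir, "pbc"),
                         modes = classify_mode(pbc))
  pc <- readr::read_csv(files[["parallel_coords"]], show_col_types = FALSE)
  expect_equal(nrow(pc), 48)
  back <- dplyr::inner_join(
    pc, pbc, by = c("compound", "conc_mM", "condition"),
    suffix = c(".csv", "")
  )
  expect_lt(max(abs(back$log2_growth.csv - back$log2_growth)), 1e-9)
  expect_lt(max(abs(back$pbc.csv - back$pbc)), 1e-9)
  radar <- jsonlite::read_json(files[["radar"]])
  expect_length(radar, 3)                       # condition blocks
  expect_length(radar[[1]]$axes_conc_mM, 4)     # concentration axes
  expect_length(radar[[1]]$series, 4)           # one series per compound
  expect_length(radar[[1]]$series[[1]]$pbc, 4)
  expect_error(export_charts(pbc[0, ], file.path(dir, "x")),
               class = "format_error")
})
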