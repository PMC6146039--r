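#' Experimental-design summary
#'
#' Computes the design arithmetic of a screening run from its
#' configuration: total plants, replicate seedlings per variant and
#' imaging timepoints per plant.
#'
#' @param n_plates Total multi-well plates in the run.
#' @param wells_per_plate Wells (one plant each) per plate.
#' @param replicate_plates Plates per variant x condition.
#' @param images_per_day Imaging sessions per day.
#' @param n_days Imaging days.
#' @return One-row tibble: `total_plants`, `replicate_seedlings`,
#'   `n_timepoints`.
#' @examples
#' design_summary(119, 48, 2, 2, 7)  # 5712 plants, 96 replicates, 14 points
#' @export
design_summary <- function(n_plates = 119, wells_per_plate = 48,
                           replicate_plates = 2, images_per_day = 2,
                           n_days = 7) {
  tibble(
    total_plants = as.integer(n_plates * wells_per_plate),
    replicate_seedlings = as.integer(replicate_plates * wells_per_plate),
    n_timepoints = as.integer(images_per_day * n_days)
  )
}

## Assign wells to groups: each group gets floor(n/k) wells, remainder to
## the control (first) group. Deterministic, row-major well order.
allocate_wells <- function(wells, groups) {
  k <- nrow(groups)
  reps <- length(wells) %/% k
  if (reps < 2) {
    stop_phenoplate("fewer than 2 replicate wells per group", "scenario_error")
  }
  extra <- length(wells) - reps * k
  sizes <- rep(reps, k)
  sizes[1] <- sizes[1] + extra
  idx <- rep(seq_len(k), times = sizes)
  bind_cols(tibble(well = wells), groups[idx, ])
}

#' Scenario for a full synthetic biostimulant screen
#'
#' Bundles everything needed to emulate one complete screening run with
#' planted ground truth: a seed scan + MTT plate per growth condition
#' (germination assay) and two 48-well growth plates per condition
#' (rosette assay), with treatment effects applied per variant. The
#' defaults define a planted-effect verification run: per-plant noise is
#' kept low (initial-area CV 4 %, per-well MTT effect CV 2 %, no
#' mortality) so that the recovered PBC index isolates pipeline bias
#' rather than biological variance, and every planted mode of action is
#' unambiguous.
#'
#' @param effects Planted-effect table (default [default_screen_effects()]).
#' @param conditions Growth conditions screened.
#' @param mtt_mu Named per-condition baseline per-seed signal (OD); the
#'   dose-dependent decrease with salinity.
#' @param n_days Imaging days for the rosette assay.
#' @param n_growth_plates,n_mtt_plates Replicate plates per condition for
#'   the rosette and germination assays. The real design uses 96 replicate
#'   seedlings per variant; these defaults give 16 growth wells and 11 MTT
#'   wells per variant, enough replication for a stable per-variant index
#'   at desk scale.
#' @param a0_cv,well_effect_cv,mortality150 Noise knobs for the growth and
#'   MTT generators.
#' @param rng_seed Integer seed for all generators.
#' @return List of class `screen_scenario`.
#' @export
screen_scenario <- function(effects = default_screen_effects(),
                            conditions = conditions_enum(),
                            mtt_mu = c(control = 0.019, NaCl75 = 0.014,
                                       NaCl150 = 0.008),
                            n_days = 7, n_growth_plates = 6, n_mtt_plates = 2,
                            a0_cv = 0.04, well_effect_cv = 0.02,
                            mortality150 = 0, rng_seed = 1) {
  structure(as.list(environment()), class = "screen_scenario")
}

#' Planted treatment effects used by the default synthetic screen
#'
#' Four compounds x four concentrations x three conditions, with one
#' unambiguous planted mode of action per compound: `Put` combined
#' (positive everywhere), `Spd` growth promotor (positive only without
#' salt), `Spm` growth inhibitor (negative without salt), `Pro` stress
#' alleviator (positive only under salt). Concentration scales the log2
#' effect sizes; all planted PBC values sit at least 0.3 log2 units away
#' from the +/-0.1 neutral dead zone.
#'
#' @return Tibble `compound`, `conc_mM`, `condition`, `germination_x`,
#'   `establishment_x`, `growth_x`, `color_x`.
#' @export
default_screen_effects <- function() {
  conc <- c(0.001, 0.01, 0.1, 1)
  conc_f <- c(0.6, 0.85, 1, 0.9)  # bell-shaped dose response on the log2 scale
  base <- dplyr::tribble(
    ~compound, ~condition, ~germination_x, ~establishment_x, ~growth_x, ~color_x,
    "Put", "control", 1.00, 1.20, 1.50, 1.10,
    "Put", "NaCl75",  1.30, 1.00, 1.50, 1.15,
    "Put", "NaCl150", 1.30, 1.00, 1.50, 1.15,
    "Spd", "control", 1.00, 1.15, 1.40, 1.05,
    "Spd", "NaCl75",  1.00, 1.00, 0.90, 1.00,
    "Spd", "NaCl150", 1.00, 1.00, 0.90, 1.00,
    "Spm", "control", 1.00, 0.85, 0.60, 0.95,
    "Spm", "NaCl75",  1.00, 1.00, 0.90, 1.00,
    "Spm", "NaCl150", 1.00, 1.00, 0.90, 1.00,
    "Pro", "control", 1.00, 1.00, 0.95, 1.00,
    "Pro", "NaCl75",  1.25, 1.00, 1.40, 1.10,
    "Pro", "NaCl150", 1.25, 1.00, 1.40, 1.10
  )
  expand_grid(base, tibble(conc_mM = conc, conc_f = conc_f)) |>
    mutate(across(dplyr::ends_with("_x"), ~ .x^.data$conc_f)) |>
    select("compound", "conc_mM", "condition", "germination_x",
           "establishment_x", "growth_x", "color_x") |>
    arrange(.data$condition, .data$compound, .data$conc_mM)
}

#' Generate all raw data of a synthetic screen
#'
#' Produces, per condition: a 96-well seed scan (with true counts), an
#' MTT absorbance plate generated from those true counts with planted
#' germination effects, and two 48-well growth-plate image series with
#' planted establishment/growth/colour effects. The analytic expected PBC
#' index per variant is included.
#'
#' @param scenario A [screen_scenario()].
#' @return List with per-condition elements under `$conditions[[cond]]`
#'   (`seed_scan`, `mtt`, `mtt_treatments`, `growth` — a list of
#'   per-plate generator outputs), plus `$expected` (analytic PBC) and
#'   `$scenario`.
#' @export
generate_screen <- function(scenario = screen_scenario()) {
  stopifnot(inherits(scenario, "screen_scenario"))
  variants <- scenario$effects |> distinct(.data$compound, .data$conc_mM)
  out <- list(scenario = scenario, conditions = list())
  seed_k <- scenario$rng_seed
  n_mtt <- scenario$n_mtt_plates
  n_gp <- scenario$n_growth_plates
  for (ci in seq_along(scenario$conditions)) {
    cond <- scenario$conditions[ci]
    groups <- bind_rows(tibble(compound = "none", conc_mM = 0), variants) |>
      mutate(condition = cond)
    cseed <- seed_k + 100 * ci
    ## --- germination assay: seed scans + MTT plates ---
    mtt_plates <- map(seq_len(n_mtt), function(p) {
      lay96 <- plate_layout_96(plate_id = sprintf("mtt_%s_%d", cond, p))
      mtt_tm <- treatment_map(allocate_wells(well_labels(lay96), groups), lay96)
      scan <- generate_seed_scan(
        seed_scan_scenario(rng_seed = cseed + 2 * p),
        lay96
      )
      mults <- mtt_tm |>
        left_join(scenario$effects, by = c("compound", "conc_mM", "condition")) |>
        mutate(mult = if_else(is.na(.data$germination_x), 1, .data$germination_x)) |>
        select("well", "mult")
      mtt <- generate_mtt_table(
        mtt_scenario(mu_seed = scenario$mtt_mu[[cond]],
                     well_effect_cv = scenario$well_effect_cv,
                     rng_seed = cseed + 2 * p + 1),
        counts = scan$manifest[c("well", "n_seeds")],
        treatments = mtt_tm, mu_multiplier = mults,
        plate_id = sprintf("mtt_%s_%d", cond, p)
      )
      list(seed_scan = scan, mtt = mtt, treatments = mtt_tm)
    })
    ## --- rosette assay: replicate 48-well plates, wells allocated
    ##     across the whole condition so every variant spans plates ---
    lay48 <- map(seq_len(n_gp), ~ plate_layout_48(sprintf("growth_%s_%d", cond, .x)))
    all_wells <- unlist(map(seq_len(n_gp), function(p) {
      paste0("P", p, "_", well_labels(lay48[[p]]))
    }))
    alloc <- allocate_wells(all_wells, groups)
    mort <- c(control = 0, NaCl75 = 0, NaCl150 = scenario$mortality150)
    growth <- map(seq_len(n_gp), function(p) {
      tm <- alloc |>
        filter(stringr::str_starts(.data$well, paste0("P", p, "_"))) |>
        mutate(well = sub("^P[0-9]+_", "", .data$well)) |>
        treatment_map(lay48[[p]])
      generate_growth_images(
        growth_scenario(effects = scenario$effects, a0_cv = scenario$a0_cv,
                        mortality = mort, n_days = scenario$n_days,
                        rng_seed = cseed + 40 + p),
        layout = lay48[[p]], treatments = tm
      )
    })
    out$conditions[[cond]] <- list(mtt_plates = mtt_plates, growth = growth)
  }
  expected_all <- generate_trait_table(scenario$effects)$expected
  out$expected <- expected_all
  out
}

#' Run the full analysis pipeline on generated (in-memory) screen data
#'
#' The analysis half of the end-to-end loop: counts seeds from the scan
#' images, normalizes the MTT absorbance per seed, builds growth series
#' and summaries from the image stacks, measures final-day colour
#' indices, assembles the trait table and computes the PBC index and mode
#' classification. All inputs come from [generate_screen()]; nothing is
#' read from the generator manifests except well identities.
#'
#' @param screen Output of [generate_screen()].
#' @param solidity_threshold,exg_threshold,min_alive_area,epsilon Stage
#'   parameters (defaults as in the individual stage functions).
#' @return List of tibbles: `counts`, `germination`, `growth_series`,
#'   `growth`, `color`, `mortality`, `traits`, `pbc`, `modes`.
#' @export
run_screen <- function(screen, solidity_threshold = 0.9, exg_threshold = 0.10,
                       min_alive_area = 25, epsilon = 0.1) {
  counts_all <- list(); germ_all <- list(); growth_all <- list()
  series_all <- list(); color_all <- list()
  for (cond in names(screen$conditions)) {
    sc <- screen$conditions[[cond]]
    for (mp in sc$mtt_plates) {
      pid <- attr(mp$mtt$plate, "plate_id")
      counts <- count_plate_seeds(mp$seed_scan$image,
                                  solidity_threshold = solidity_threshold)
      germ <- per_seed_absorbance(mp$mtt$plate, counts,
                                  treatments = mp$treatments)
      counts_all[[pid]] <- counts
      germ_all[[pid]] <- germ
    }
    for (g in sc$growth) {
      plate_id <- g$images[[1]]$layout$plate_id
      areas <- measure_plate_growth(g$images, threshold = exg_threshold)
      series <- build_timeseries(areas, min_alive_area = min_alive_area,
                                 treatments = g$treatments)
      growth_all[[plate_id]] <- summarize_growth(series) |>
        mutate(plate_id = plate_id)
      series_all[[plate_id]] <- series |> mutate(plate_id = plate_id)
      color_all[[plate_id]] <- measure_plate_indices(
        g$images[[length(g$images)]], threshold = exg_threshold,
        treatments = g$treatments) |>
        mutate(plate_id = plate_id)
    }
  }
  growth <- list_rbind(growth_all)
  series <- list_rbind(series_all)
  color <- list_rbind(color_all)
  germination <- list_rbind(germ_all)
  traits <- build_trait_table(germination, growth, color)
  pbc <- compute_pbc(traits, epsilon = epsilon)
  modes <- classify_mode(pbc, epsilon = epsilon)
  list(counts = list_rbind(counts_all), germination = germination,
       growth_series = series, growth = growth, color = color,
       mortality = mortality_fraction(series),
       traits = traits, pbc = pbc, modes = modes)
}

#' Write a generated screen to disk as pipeline input files
#'
#' Lays out the file tree [run_pipeline()] consumes: per condition a seed
#' scan PNG, a layout+treatments YAML and an absorbance CSV for the MTT
#' assay, and per growth plate a directory of frame PNGs (timestamps
#' encoded in the filenames, `frame_t<hours>h.png`) with its own layout
#' YAML; plus a top-level `run_config.yaml`.
#'
#' @param screen Output of [generate_screen()].
#' @param dir Output directory (created if needed).
#' @return Path of the written run config, invisibly.
#' @export
write_screen <- function(screen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(seed = screen$scenario$rng_seed, out_dir = "results",
              params = list(solidity_threshold = 0.9, exg_threshold = 0.10,
                            min_alive_area = 25, epsilon = 0.1),
              conditions = list())
  for (cond in names(screen$conditions)) {
    sc <- screen$conditions[[cond]]
    mtt_entries <- map(sc$mtt_plates, function(mp) {
      pid <- attr(mp$mtt$plate, "plate_id")
      scan_path <- file.path(dir, paste0("scan_", pid, ".png"))
      write_plate_image(mp$seed_scan$image, scan_path)
      layout_path <- file.path(dir, paste0(pid, ".yaml"))
      write_layout_yaml(mp$seed_scan$image$layout, layout_path,
                        treatments = mp$treatments)
      abs_path <- file.path(dir, paste0(pid, ".csv"))
      write_absorbance_csv(mp$mtt$plate, abs_path, dialect = "grid8x12")
      list(seed_scan = basename(scan_path), layout = basename(layout_path),
           absorbance = basename(abs_path))
    })
    plates <- map(sc$growth, function(g) {
      pid <- g$images[[1]]$layout$plate_id
      pdir <- file.path(dir, pid)
      dir.create(pdir, showWarnings = FALSE)
      for (img in g$images) {
        write_plate_image(img, file.path(pdir, sprintf("frame_t%06.1fh.png",
                                                       img$timestamp_h)))
      }
      lpath <- file.path(dir, paste0(pid, ".yaml"))
      write_layout_yaml(g$images[[1]]$layout, lpath, treatments = g$treatments)
      list(layout = basename(lpath), images_dir = pid)
    })
    cfg$conditions[[cond]] <- list(mtt_plates = mtt_entries,
                                   growth_plates = plates)
  }
  cfg_path <- file.path(dir, "run_config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}

## parse "frame_t0042.0h.png" -> 42
parse_frame_time <- function(path) {
  m <- stringr::str_match(basename(path), "t([0-9]+\\.?[0-9]*)h")
  as.numeric(m[, 2])
}

#' Run the full pipeline from a run-config file
#'
#' Reads the config written by [write_screen()] (or hand-written to the
#' same schema), executes every stage, and writes all result tables plus
#' a JSON run manifest to the config's `out_dir`. Re-running with
#' identical inputs reproduces identical outputs: the analysis stages use
#' no random numbers.
#'
#' @param config Path to a `run_config.yaml`, or an equivalent list.
#' @param base_dir Directory paths in the config are relative to
#'   (defaults to the config file's directory).
#' @return Invisibly, the list of result tibbles (see [run_screen()]),
#'   after writing `counts.csv`, `germination.csv`, `growth.csv`,
#'   `indices.csv`, `traits.csv`, `pbc_index.csv`,
#'   `pbc_parallel_coords.csv`, `pbc_radar.json` and `manifest.json`.
#' @export
run_pipeline <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop_phenoplate(paste0("config file not found: ", config), "config_error")
    }
    base_dir <- base_dir %||% dirname(config)
    config <- yaml::read_yaml(config)
  }
  base_dir <- base_dir %||% "."
  p <- config$params %||% list()
  ## validate referenced inputs before computing anything
  for (cond in names(config$conditions)) {
    cc <- config$conditions[[cond]]
    for (f in c(unlist(map(cc$mtt_plates, function(m) c(m$seed_scan, m$layout, m$absorbance))),
                unlist(map(cc$growth_plates, "layout")))) {
      if (!file.exists(file.path(base_dir, f))) {
        stop_phenoplate(paste0("missing input for condition ", cond, ": ", f),
                        "config_error")
      }
    }
  }
  screen <- list(scenario = list(rng_seed = config$seed %||% NA), conditions = list())
  for (cond in names(config$conditions)) {
    cc <- config$conditions[[cond]]
    mtt_plates <- map(cc$mtt_plates, function(m) {
      ml <- read_layout_yaml(file.path(base_dir, m$layout))
      scan <- read_plate_image(file.path(base_dir, m$seed_scan), ml$layout, 0)
      plate <- read_absorbance_csv(file.path(base_dir, m$absorbance))
      list(seed_scan = list(image = scan), mtt = list(plate = plate),
           treatments = ml$treatments)
    })
    growth <- map(cc$growth_plates, function(gp) {
      gl <- read_layout_yaml(file.path(base_dir, gp$layout))
      files <- sort(list.files(file.path(base_dir, gp$images_dir),
                               pattern = "\\.png$", full.names = TRUE))
      if (!length(files)) {
        stop_phenoplate(paste0("no frames in ", gp$images_dir), "config_error")
      }
      imgs <- map(files, ~ read_plate_image(.x, gl$layout, parse_frame_time(.x)))
      list(images = imgs, treatments = gl$treatments)
    })
    screen$conditions[[cond]] <- list(mtt_plates = mtt_plates, growth = growth)
  }
  res <- run_screen(screen,
                    solidity_threshold = p$solidity_threshold %||% 0.9,
                    exg_threshold = p$exg_threshold %||% 0.10,
                    min_alive_area = p$min_alive_area %||% 25,
                    epsilon = p$epsilon %||% 0.1)
  out_dir <- file.path(base_dir, config$out_dir %||% "results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results_table(res$counts, file.path(out_dir, "counts.csv"))
  write_results_table(res$germination, file.path(out_dir, "germination.csv"))
  write_results_table(res$growth, file.path(out_dir, "growth.csv"))
  write_results_table(res$color, file.path(out_dir, "indices.csv"))
  write_results_table(res$traits, file.path(out_dir, "traits.csv"))
  write_results_table(left_join(res$pbc, res$modes, by = c("compound", "conc_mM")),
                      file.path(out_dir, "pbc_index.csv"))
  export_charts(res$pbc, file.path(out_dir, "pbc"), modes = res$modes)
  write_run_manifest(file.path(out_dir, "manifest.json"),
                     inputs = config$conditions, params = p,
                     seed = config$seed)
  invisible(res)
}
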