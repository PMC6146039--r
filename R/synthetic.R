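## Synthetic-data generators: every assay stage can be exercised against
## exact ground truth (drawn counts, per-well signal, per-frame areas),
## with one seeded RNG stream per scenario so identical seeds give
## bit-identical artifacts.

#' Scenario for a synthetic 96-well seed scan
#'
#' Emulates the 0 h plate scan used for seed counting: dark ellipsoidal
#' seeds on light agarose inside circular wells, with a controllable
#' fraction of seeds dispensed as touching clusters. The per-well count
#' distribution defaults to the multi-step-pipette dispensing regime
#' (mean 21, SD 5.4 seeds/well, truncated at zero and rounded).
#'
#' @param seeds_per_well_mean,seeds_per_well_sd Count distribution per well.
#' @param seed_axis_a_px,seed_axis_b_px Mean semi-major/semi-minor axis of a
#'   seed ellipse (px); each seed's axes get `axis_jitter` relative noise.
#' @param axis_jitter Relative SD of the axis jitter.
#' @param cluster_fraction Probability that a seed is placed touching an
#'   already-placed seed, forming a cluster.
#' @param seed_color,background_color RGB triples in `[0, 1]`.
#' @param color_jitter Per-seed relative colour jitter.
#' @param noise_sd Per-pixel sensor noise SD.
#' @param rng_seed Integer seed; identical seeds give identical plates.
#' @return A list of class `seed_scan_scenario`.
#' @export
seed_scan_scenario <- function(seeds_per_well_mean = 21,
                               seeds_per_well_sd = 5.4,
                               seed_axis_a_px = 6, seed_axis_b_px = 4.2,
                               axis_jitter = 0.08,
                               cluster_fraction = 0.10,
                               seed_color = c(0.36, 0.24, 0.13),
                               background_color = c(0.91, 0.89, 0.85),
                               color_jitter = 0.04,
                               noise_sd = 0.01,
                               rng_seed = 1) {
  structure(as.list(environment()), class = "seed_scan_scenario")
}

## clamp to [0,1] preserving dim
clip01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }

## pixels (y, x within a bounding box) covered by an ellipse
ellipse_pixels <- function(cx, cy, a, b, theta, xmax, ymax) {
  ext <- max(a, b) + 1
  xs <- max(1, floor(cx - ext)):min(xmax, ceiling(cx + ext))
  ys <- max(1, floor(cy - ext)):min(ymax, ceiling(cy + ext))
  dx <- rep(xs, each = length(ys)) - cx
  dy <- rep(ys, times = length(xs)) - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  keep <- u^2 + v^2 <= 1
  cbind(y = rep(ys, times = length(xs))[keep], x = rep(xs, each = length(ys))[keep])
}

## radius of an ellipse along direction phi (from its own frame angle theta)
ellipse_radius_along <- function(a, b, theta, phi) {
  c2 <- cos(phi - theta)^2
  s2 <- sin(phi - theta)^2
  1 / sqrt(c2 / a^2 + s2 / b^2)
}

#' Generate a synthetic seed-scan plate image with known counts
#'
#' Seeds are drawn per well from the scenario's count distribution; free
#' seeds are placed with a separation margin so they never touch, and
#' cluster seeds are attached to a host seed with a partial overlap so the
#' union is a non-convex two-lobed object — exactly the geometry the
#' solidity rule has to split. The manifest records the exact drawn count
#' per well.
#'
#' @param scenario A [seed_scan_scenario()].
#' @param layout A [plate_layout()] (default [plate_layout_96()]).
#' @return List with `image` (a [plate_image()]) and `manifest` (tibble
#'   `well`, `n_seeds`, `n_objects`, `n_clusters`, `mean_seed_area_px`).
#' @export
generate_seed_scan <- function(scenario = seed_scan_scenario(),
                               layout = plate_layout_96()) {
  stopifnot(inherits(scenario, "seed_scan_scenario"))
  set.seed(scenario$rng_seed)
  h <- layout$image_size[1]; w <- layout$image_size[2]
  px <- array(rep(scenario$background_color, each = h * w), c(h, w, 3))
  rmax <- layout$radius_px
  margin <- 1.4 * scenario$seed_axis_a_px * (1 + 3 * scenario$axis_jitter)
  if (rmax - margin < scenario$seed_axis_a_px) {
    stop_phenoplate("seeds too large for the well radius", "scenario_error")
  }
  ## well rims for visual realism (outside the analysed interior)
  rim <- function(cx, cy) {
    xs <- max(1, floor(cx - rmax - 3)):min(w, ceiling(cx + rmax + 3))
    ys <- max(1, floor(cy - rmax - 3)):min(h, ceiling(cy + rmax + 3))
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    sel <- d2 > rmax^2 & d2 <= (rmax + 2.5)^2
    idx <- which(sel, arr.ind = TRUE)
    cbind(y = ys[idx[, 1]], x = xs[idx[, 2]])
  }
  manifest <- vector("list", nrow(layout$wells))
  for (wi in seq_len(nrow(layout$wells))) {
    wl <- layout$wells[wi, ]
    rp <- rim(wl$cx, wl$cy)
    for (ch in 1:3) px[cbind(rp, ch)] <- 0.55
    ## draw the count (truncated normal, rounded)
    n <- -1
    while (n < 0) {
      n <- round(rnorm(1, scenario$seeds_per_well_mean, scenario$seeds_per_well_sd))
    }
    placed <- list()   # each: cx, cy, a, b, theta, host-able flag
    n_clusters <- 0
    areas <- numeric(0)
    k <- 0
    while (k < n) {
      k <- k + 1
      a <- scenario$seed_axis_a_px * (1 + rnorm(1, 0, scenario$axis_jitter))
      b <- scenario$seed_axis_b_px * (1 + rnorm(1, 0, scenario$axis_jitter))
      theta <- runif(1, 0, pi)
      hosts <- which(vapply(placed, function(p) p$free, logical(1)))
      as_cluster <- length(hosts) > 0 && runif(1) < scenario$cluster_fraction
      attach_to_host <- function(hidx) {
        ## near-perpendicular side attachment at tangent distance: the
        ## union is either a clearly waisted two-lobed object or (rarely)
        ## two just-separate seeds — both are counted correctly downstream
        host <- placed[[hidx]]
        theta <<- host$theta + runif(1, 0.42 * pi, 0.5 * pi) * sample(c(-1, 1), 1)
        phi <- host$theta + pi / 2 + runif(1, -pi / 8, pi / 8) + sample(c(0, pi), 1)
        d <- 1.08 * (ellipse_radius_along(host$a, host$b, host$theta, phi) +
                       ellipse_radius_along(a, b, theta, phi + pi))
        c(host$cx + d * cos(phi), host$cy + d * sin(phi))
      }
      ## an attachment must stay inside the well and clear of every seed
      ## other than its host (no accidental triples)
      attach_ok <- function(pos, hidx) {
        if (sqrt((pos[1] - wl$cx)^2 + (pos[2] - wl$cy)^2) > rmax - margin) {
          return(FALSE)
        }
        others <- setdiff(seq_along(placed), hidx)
        all(vapply(others, function(j) {
          p <- placed[[j]]
          sqrt((pos[1] - p$cx)^2 + (pos[2] - p$cy)^2) >= 1.3 * (a + p$a)
        }, logical(1)))
      }
      if (as_cluster) {
        hidx <- hosts[sample.int(length(hosts), 1)]
        pos <- attach_to_host(hidx)
        cx <- pos[1]; cy <- pos[2]
        if (!attach_ok(pos, hidx)) {
          k <- k - 1; next  # retry this seed elsewhere
        }
        placed[[hidx]]$free <- FALSE
        placed[[length(placed) + 1]] <- list(cx = cx, cy = cy, a = a, b = b,
                                             theta = theta, free = FALSE)
        n_clusters <- n_clusters + 1
      } else {
        ok <- FALSE
        for (try in 1:300) {
          rr <- (rmax - margin) * sqrt(runif(1))
          ang <- runif(1, 0, 2 * pi)
          cx <- wl$cx + rr * cos(ang); cy <- wl$cy + rr * sin(ang)
          clear <- all(vapply(placed, function(p) {
            sqrt((cx - p$cx)^2 + (cy - p$cy)^2) >= 1.3 * (a + p$a)
          }, logical(1)))
          if (clear) { ok <- TRUE; break }
        }
        if (!ok && length(hosts)) {
          ## crowded well: dispense onto an existing seed as a cluster,
          ## as a dense suspension would
          hidx <- hosts[sample.int(length(hosts), 1)]
          pos <- attach_to_host(hidx)
          cx <- pos[1]; cy <- pos[2]
          if (!attach_ok(pos, hidx)) {
            k <- k - 1; next
          }
          placed[[hidx]]$free <- FALSE
          placed[[length(placed) + 1]] <- list(cx = cx, cy = cy, a = a, b = b,
                                               theta = theta, free = FALSE)
          n_clusters <- n_clusters + 1
        } else if (!ok) {
          stop_phenoplate(sprintf(
            "could not place %d seeds in well %s: well too crowded for the seed size",
            n, wl$well), "scenario_error")
        } else {
          placed[[length(placed) + 1]] <- list(cx = cx, cy = cy, a = a, b = b,
                                               theta = theta, free = TRUE)
        }
      }
      p <- placed[[length(placed)]]
      pix <- ellipse_pixels(p$cx, p$cy, p$a, p$b, p$theta, w, h)
      areas <- c(areas, nrow(pix))
      col <- pmin(1, pmax(0, scenario$seed_color *
                            (1 + rnorm(3, 0, scenario$color_jitter))))
      for (ch in 1:3) px[cbind(pix, ch)] <- col[ch]
    }
    manifest[[wi]] <- tibble(
      well = wl$well, n_seeds = as.integer(n),
      n_objects = as.integer(n - n_clusters), n_clusters = as.integer(n_clusters),
      mean_seed_area_px = if (length(areas)) mean(areas) else NA_real_
    )
  }
  if (scenario$noise_sd > 0) {
    px <- px + array(rnorm(h * w * 3, 0, scenario$noise_sd), c(h, w, 3))
  }
  px <- clip01(px)
  list(image = plate_image(px, layout, timestamp_h = 0),
       manifest = list_rbind(manifest))
}

#' Scenario for a synthetic MTT absorbance plate
#'
#' Emulates the dual-wavelength read of the germination assay: each
#' germinated seed contributes a formazan signal drawn from
#' `N(mu_seed, sd_seed^2)` (defaults from the 24 h assay: 0.019 +/- 0.002
#' OD/seed; use 0.041 +/- 0.003 for 48 h), non-germinated seeds contribute
#' near-zero, wells share a reference baseline at 690 nm, and both
#' wavelengths carry independent reader noise. A lognormal per-well
#' biological effect (`well_effect_cv`) reproduces the between-well
#' dispersion of per-seed activity seen in real plates.
#'
#' @param mu_seed,sd_seed Per-seed formazan signal (OD).
#' @param mu_nongerm,sd_nongerm Signal of a non-germinated seed.
#' @param germination_fraction Either a single fraction or a named vector
#'   by condition (`control`, `NaCl75`, `NaCl150`).
#' @param well_effect_cv Relative SD of the per-well multiplicative
#'   biological effect on `mu_seed` (0 disables it).
#' @param baseline_a690 Reference-wavelength baseline (OD).
#' @param reader_noise_sd Reader noise SD per wavelength read.
#' @param timepoint_h Assay timepoint in hours (24 or 48).
#' @param rng_seed Integer seed.
#' @return A list of class `mtt_scenario`.
#' @export
mtt_scenario <- function(mu_seed = 0.019, sd_seed = 0.002,
                         mu_nongerm = 0.001, sd_nongerm = 0.0005,
                         germination_fraction = 1,
                         well_effect_cv = 0.09,
                         baseline_a690 = 0.05, reader_noise_sd = 0.003,
                         timepoint_h = 24, rng_seed = 1) {
  structure(as.list(environment()), class = "mtt_scenario")
}

#' Generate a synthetic MTT absorbance plate from true seed counts
#'
#' @param scenario An [mtt_scenario()].
#' @param counts Tibble `well`, `n_seeds` (true counts, e.g. from a
#'   [generate_seed_scan()] manifest).
#' @param treatments Optional [treatment_map()]; used to pick the
#'   germination fraction by condition and to apply `mu_multiplier`.
#' @param mu_multiplier Optional tibble `well`, `mult` scaling `mu_seed`
#'   per well (planted germination effects).
#' @param plate_id Plate identifier for the output.
#' @return List with `plate` (an [absorbance_plate()]) and `manifest`
#'   (tibble `well`, `n_seeds`, `n_germinated`, `true_signal`, `net_abs`).
#' @export
generate_mtt_table <- function(scenario = mtt_scenario(), counts,
                               treatments = NULL, mu_multiplier = NULL,
                               plate_id = "mtt_plate") {
  stopifnot(inherits(scenario, "mtt_scenario"),
            all(c("well", "n_seeds") %in% names(counts)))
  set.seed(scenario$rng_seed)
  gf <- scenario$germination_fraction
  rows <- map(seq_len(nrow(counts)), function(i) {
    wl <- counts$well[i]; n <- counts$n_seeds[i]
    g <- if (length(gf) == 1 || is.null(treatments)) {
      gf[[1]]
    } else {
      cond <- treatments$condition[treatments$well == wl]
      (gf[[cond]] %||% gf[[1]])
    }
    mult <- 1
    if (!is.null(mu_multiplier)) {
      m <- mu_multiplier$mult[mu_multiplier$well == wl]
      if (length(m)) mult <- m
    }
    well_mu <- scenario$mu_seed * mult *
      if (scenario$well_effect_cv > 0) exp(rnorm(1, 0, scenario$well_effect_cv)) else 1
    n_germ <- if (n > 0) rbinom(1, n, g) else 0L
    signal <- sum(rnorm(n_germ, well_mu, scenario$sd_seed)) +
      sum(rnorm(n - n_germ, scenario$mu_nongerm, scenario$sd_nongerm))
    a690 <- scenario$baseline_a690 + rnorm(1, 0, scenario$reader_noise_sd)
    a570 <- scenario$baseline_a690 + signal + rnorm(1, 0, scenario$reader_noise_sd)
    tibble(well = wl, n_seeds = as.integer(n), n_germinated = as.integer(n_germ),
           true_signal = signal, a570 = a570, a690 = a690,
           net_abs = a570 - a690)
  }) |> list_rbind()
  plate <- absorbance_plate(rows[c("well", "a570", "a690")],
                            plate_id = plate_id,
                            timepoint_h = scenario$timepoint_h)
  list(plate = plate,
       manifest = rows[c("well", "n_seeds", "n_germinated", "true_signal", "net_abs")])
}

#' Scenario for synthetic rosette growth image series
#'
#' Emulates the twice-daily top-view imaging of 48-well plates: each plant
#' grows exponentially with a higher daytime (10:00-16:00) than overnight
#' rate, salt stress suppresses the rate and shifts the leaf colour from
#' green toward yellow, and severe stress can kill plants (the rendered
#' blob turns brown and shrivels, so its green area collapses). Planted
#' treatment effects enter as per-variant multipliers on the four traits.
#'
#' Rosettes are rendered as lobed star-convex blobs whose pixel count
#' equals the rounded true area exactly — the manifest area is the
#' rendered pixel count, so segmentation accuracy can be judged against
#' exact ground truth.
#'
#' @param a0_px Mean establishment (time-zero) area, px.
#' @param a0_cv Relative SD of per-plant initial area (lognormal).
#' @param r_day,r_night Hourly relative growth rates for the daytime
#'   (10:00-16:00) and overnight intervals.
#' @param stress_suppression Named multipliers on the growth rate under
#'   `NaCl75` / `NaCl150`.
#' @param mortality Named per-plant death probabilities by condition.
#' @param n_days Imaging days; frames at `times_of_day` each day.
#' @param times_of_day Imaging hours-of-day (default 10:00 and 16:00).
#' @param plant_color Healthy leaf RGB.
#' @param stress_color_shift Named 0-1 mix toward yellow by condition.
#' @param lobes,lobe_depth Shape of the rosette outline.
#' @param effects Optional planted-effect tibble (`compound`, `conc_mM`,
#'   `condition`, `germination_x`, `establishment_x`, `growth_x`,
#'   `color_x`); `NULL` means no treatment effects.
#' @param noise_sd Per-pixel sensor noise SD.
#' @param rng_seed Integer seed.
#' @return A list of class `growth_scenario`.
#' @export
growth_scenario <- function(a0_px = 300, a0_cv = 0.2,
                            r_day = 0.012, r_night = 0.008,
                            stress_suppression = c(NaCl75 = 0.7, NaCl150 = 0.4),
                            mortality = c(control = 0, NaCl75 = 0.02, NaCl150 = 0.25),
                            n_days = 7, times_of_day = c(10, 16),
                            plant_color = c(0.20, 0.55, 0.16),
                            stress_color_shift = c(NaCl75 = 0.25, NaCl150 = 0.5),
                            lobes = 5, lobe_depth = 0.15,
                            effects = NULL, noise_sd = 0.01, rng_seed = 1) {
  structure(as.list(environment()), class = "growth_scenario")
}

#' Imaging timestamps of a growth scenario
#' @param scenario A [growth_scenario()].
#' @return Hours since the first frame (first frame = 0).
#' @export
growth_timestamps <- function(scenario) {
  tod <- sort(scenario$times_of_day)
  as.vector(vapply(seq_len(scenario$n_days) - 1,
                   function(d) d * 24 + (tod - tod[1]), numeric(length(tod))))
}

## yellowish target for the stress colour shift
.yellow_leaf <- c(0.55, 0.52, 0.18)
.dead_brown <- c(0.45, 0.34, 0.24)
.agar_color <- c(0.82, 0.76, 0.70)

## solve for the green channel that scales GLI by `mult` at fixed R and B
scale_gli_color <- function(col, mult) {
  k <- mult * (2 * col[2] - col[1] - col[3]) / (2 * col[2] + col[1] + col[3])
  if (k >= 1) stop_phenoplate("colour effect too large: GLI target >= 1", "scenario_error")
  g <- (col[1] + col[3]) * (1 + k) / (2 * (1 - k))
  if (g < 0 || g > 1) stop_phenoplate("colour effect out of gamut", "scenario_error")
  c(col[1], g, col[3])
}

#' Generate a synthetic rosette growth image series with exact areas
#'
#' @param scenario A [growth_scenario()].
#' @param layout A [plate_layout()] (default [plate_layout_48()]).
#' @param treatments Optional [treatment_map()] assigning each well a
#'   variant and condition; default: untreated control everywhere.
#' @param render Set `FALSE` to produce only the ground-truth manifest
#'   (no images, no well-capacity constraint) — useful for studying the
#'   area model itself.
#' @return List with `images` (list of [plate_image()] ordered by time),
#'   `manifest` (tibble `well`, `timestamp_h`, `area_px` — the exact
#'   rendered green pixel count, 0 once dead — plus `true_area` (the
#'   continuous model area), `status`), `treatments`, and `params`
#'   (per-well tibble of realized `a0`, rates and colours).
#' @export
generate_growth_images <- function(scenario = growth_scenario(),
                                   layout = plate_layout_48(),
                                   treatments = NULL, render = TRUE) {
  stopifnot(inherits(scenario, "growth_scenario"))
  set.seed(scenario$rng_seed)
  if (is.null(treatments)) {
    treatments <- treatment_map(
      tibble(well = well_labels(layout), compound = "none", conc_mM = 0,
             condition = "control"),
      layout
    )
  }
  ts <- growth_timestamps(scenario)
  if (length(ts) < 2) stop_phenoplate("schedule needs >= 2 frames", "scenario_error")
  tod <- sort(scenario$times_of_day)
  day_len <- tod[2] - tod[1]  # daytime interval length (h)
  t_total <- max(ts)
  ## cumulative base log-growth at each timestamp (shared day/night pattern)
  seg_rate <- function(t0, t1) {
    ## rate over [t0, t1): day rate inside the daytime window, else night
    within_day <- (t0 %% 24) < day_len - 1e-9
    if (within_day) scenario$r_day else scenario$r_night
  }
  base_logA <- cumsum(c(0, vapply(seq_along(ts)[-1], function(i) {
    seg_rate(ts[i - 1], ts[i]) * (ts[i] - ts[i - 1])
  }, numeric(1))))

  lookup_effect <- function(compound, conc, condition) {
    if (is.null(scenario$effects) || compound == "none") {
      return(c(establishment_x = 1, growth_x = 1, color_x = 1))
    }
    e <- scenario$effects |>
      filter(.data$compound == .env$compound, .data$conc_mM == .env$conc,
             .data$condition == .env$condition)
    if (nrow(e) != 1) {
      stop_phenoplate(sprintf("no planted effect for %s %g mM (%s)",
                              compound, conc, condition), "scenario_error")
    }
    c(establishment_x = e$establishment_x, growth_x = e$growth_x,
      color_x = e$color_x)
  }

  wells <- treatments$well
  params <- map(seq_along(wells), function(i) {
    tr <- treatments[i, ]
    supp <- if (tr$condition == "control") 1 else scenario$stress_suppression[[tr$condition]]
    eff <- lookup_effect(tr$compound, tr$conc_mM, tr$condition)
    a0 <- scenario$a0_px * eff[["establishment_x"]] *
      if (scenario$a0_cv > 0) exp(rnorm(1, 0, scenario$a0_cv)) else 1
    ## uniform rate offset so the planted final-area ratio equals growth_x
    delta <- log(eff[["growth_x"]] / eff[["establishment_x"]]) / t_total
    shift <- if (tr$condition == "control") 0 else scenario$stress_color_shift[[tr$condition]]
    col <- (1 - shift) * scenario$plant_color + shift * .yellow_leaf
    col <- scale_gli_color(col, eff[["color_x"]])
    p_die <- if (tr$condition %in% names(scenario$mortality)) {
      scenario$mortality[[tr$condition]]
    } else 0
    dies <- runif(1) < p_die
    death_idx <- if (dies) sample(3:max(3, length(ts) - 2), 1) else NA_integer_
    tibble(well = tr$well, a0 = a0, supp = supp, delta = delta,
           r = col[1], g = col[2], b = col[3], death_idx = death_idx,
           phase = runif(1, 0, 2 * pi))
  }) |> list_rbind()

  h <- layout$image_size[1]; w <- layout$image_size[2]
  rmax <- layout$radius_px
  ## per-well pixel ordering by lobed radial score (computed once)
  well_order <- if (!render) NULL else map(wells, function(wl) {
    reg <- well_region(layout, wl)
    xs <- reg$x0:reg$x1; ys <- reg$y0:reg$y1
    dx <- rep(xs, each = length(ys)) - reg$cx
    dy <- rep(ys, times = length(xs)) - reg$cy
    ph <- params$phase[params$well == wl]
    score <- sqrt(dx^2 + dy^2) *
      (1 + scenario$lobe_depth * cos(scenario$lobes * atan2(dy, dx) + ph))
    dist <- sqrt(dx^2 + dy^2)
    ord <- order(score)
    list(y = rep(ys, times = length(xs))[ord], x = rep(xs, each = length(ys))[ord],
         dist = dist[ord])
  })
  if (render) names(well_order) <- wells

  manifest <- vector("list", length(ts) * length(wells))
  images <- if (render) vector("list", length(ts)) else NULL
  mi <- 0
  for (fi in seq_along(ts)) {
    px <- if (render) array(rep(.agar_color, each = h * w), c(h, w, 3))
    for (wi in seq_along(wells)) {
      p <- params[wi, ]
      dead <- !is.na(p$death_idx) && fi >= p$death_idx
      true_area <- p$a0 * exp((base_logA[fi]) * p$supp + p$delta * ts[fi])
      if (!dead) {
        n_px <- max(1L, as.integer(round(true_area)))
        col <- c(p$r, p$g, p$b)
        area_green <- n_px
      } else {
        ## shrivelled brown remnant: not green, shrinking
        death_area <- p$a0 * exp(base_logA[p$death_idx] * p$supp + p$delta * ts[p$death_idx])
        n_px <- max(4L, as.integer(round(0.4 * death_area * 0.6^(fi - p$death_idx))))
        col <- .dead_brown
        area_green <- 0L
      }
      if (render) {
        wo <- well_order[[p$well]]
        if (n_px > length(wo$dist) || wo$dist[n_px] > 0.95 * rmax) {
          stop_phenoplate(sprintf("rosette exceeds well %s at t = %g h", p$well, ts[fi]),
                          "scenario_error")
        }
        sel <- seq_len(n_px)
        for (ch in 1:3) px[cbind(wo$y[sel], wo$x[sel], ch)] <- col[ch]
      }
      mi <- mi + 1
      manifest[[mi]] <- tibble(
        well = p$well, timestamp_h = ts[fi],
        area_px = as.integer(area_green),
        true_area = if (dead) 0 else true_area,
        status = if (dead) "dead" else "alive"
      )
    }
    if (render) {
      if (scenario$noise_sd > 0) {
        px <- px + array(rnorm(h * w * 3, 0, scenario$noise_sd), c(h, w, 3))
      }
      images[[fi]] <- plate_image(clip01(px), layout, timestamp_h = ts[fi])
    }
  }
  list(images = images, manifest = list_rbind(manifest),
       treatments = treatments, params = params)
}

#' Build an exact trait table from planted multipliers
#'
#' Constructs the per-variant trait table analytically (no images): trait
#' value = base value x planted multiplier, so the expected PBC index is
#' exactly the sum of log2 multipliers over the traits of each condition.
#' This is the algebra oracle for [compute_pbc()].
#'
#' @param effects Tibble `compound`, `conc_mM`, `condition`,
#'   `germination_x`, `establishment_x`, `growth_x`, `color_x` (all > 0).
#' @param base Named list of control-condition trait values.
#' @return List with `traits` (input for [compute_pbc()], controls
#'   included) and `expected` (tibble `compound`, `conc_mM`, `condition`,
#'   `pbc` with the analytic index).
#' @export
generate_trait_table <- function(effects,
                                 base = list(germination = 0.019,
                                             establishment = 300,
                                             growth = 1200, color = 0.45)) {
  mult_cols <- c("germination_x", "establishment_x", "growth_x", "color_x")
  stopifnot(all(c("compound", "conc_mM", "condition", mult_cols) %in% names(effects)))
  if (any(as.matrix(effects[mult_cols]) <= 0)) {
    stop_phenoplate("planted multipliers must be positive", "scenario_error")
  }
  conds <- unique(effects$condition)
  controls <- tibble(
    compound = "none", conc_mM = 0, condition = conds,
    germination = base$germination,
    establishment = if_else(conds == "control", base$establishment, NA_real_),
    growth = base$growth, color = base$color
  )
  variants <- effects |>
    mutate(
      germination = base$germination * .data$germination_x,
      establishment = if_else(.data$condition == "control",
                              base$establishment * .data$establishment_x, NA_real_),
      growth = base$growth * .data$growth_x,
      color = base$color * .data$color_x
    ) |>
    select("compound", "conc_mM", "condition", "germination", "establishment",
           "growth", "color")
  expected <- effects |>
    mutate(pbc = if_else(
      .data$condition == "control",
      log2(.data$germination_x) + log2(.data$establishment_x) +
        log2(.data$growth_x) + log2(.data$color_x),
      log2(.data$germination_x) + log2(.data$growth_x) + log2(.data$color_x)
    )) |>
    select("compound", "conc_mM", "condition", "pbc")
  list(traits = bind_rows(controls, variants), expected = expected)
}
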