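# phenoplate

Multi-trait high-throughput screening of seed-priming biostimulants from
plate assays, in R.

Candidate biostimulants — polyamines, amino acids, complex extracts —
are cheap to apply as seed primings but slow to characterize: does a
compound promote growth, alleviate salt stress, both, or inhibit? This
package implements the image- and absorbance-analysis side of a
plate-based screen that answers that question from two assays run under
control, moderate (75 mM NaCl) and severe (150 mM NaCl) salt:

* **Germination (96-well plates).** Tetrazolium (MTT) reduction by
  germinating seeds is read as net absorbance A₅₇₀ − A₆₉₀. Because the
  number of seeds dispensed per well varies (≈ 21 ± 5.4), the raw
  signal mostly measures seed number; phenoplate counts the seeds in
  the 0 h plate scan — channel thresholding, 8-connected components,
  and solidity (object area / convex hull area) to split touching
  clusters, `n = max(2, round(area / avg seed area))` — and normalizes
  to **absorbance per seed**, collapsing the dispensing CV severalfold.
* **Rosette growth (48-well plates, twice-daily top-view images).**
  Excess-green segmentation (2G − R − B) yields per-plant green-area
  trajectories; the relative growth rate per interval is
  RGR = (ln Aₜᵢ − ln Aₜᵢ₋₁)/(tᵢ − tᵢ₋₁), establishment is the area at
  transfer, and leaf colour is scored with the RGB vegetation indices
  NGRDI = (G−R)/(G+R), GLI = (2G−R−B)/(2G+R+B), VARI = (G−R)/(G+R−B).
* **PBC index.** Each trait is compared with the same-condition control
  as log₂(variant/control) and summed into the Plant Biostimulant
  Characterization index (4 traits without salt, 3 under stress);
  signs across conditions classify the mode of action: growth
  promotor/inhibitor, stress alleviator, or combined.

A synthetic-data generator emulates all three data streams (scan
images, absorbance tables, time-lapse image series) with exact ground
truth, so the entire pipeline is testable end to end without any
external data.

## Worked example

Count seeds on a synthetic 96-well scan and normalize an MTT plate by
the counts:

```r
library(phenoplate)

scan   <- generate_seed_scan(seed_scan_scenario(rng_seed = 1))
counts <- count_plate_seeds(scan$image)
head(counts, 4)
#>   plate_id well  n_objects n_clusters seed_count avg_seed_area_used
#> 1 plate96  A1           17          1         18                 79
#> 2 plate96  A2           17          1         18                 79
#> 3 plate96  A3           21          0         21                 79
#> 4 plate96  A4           14          2         16                 79

mtt  <- generate_mtt_table(mtt_scenario(rng_seed = 2),
                           scan$manifest[c("well", "n_seeds")])
germ <- per_seed_absorbance(mtt$plate, counts)
summarize_variant(germ, by = "net_abs")
#>   n_wells  mean     sd cv_pct
#> 1      96 0.392 0.0983   25.1
summarize_variant(germ, by = "abs_per_seed")
#>   n_wells   mean      sd cv_pct
#> 1      96 0.0191 0.00208   10.9
```

The raw per-well absorbance varies by 25 % (the dispensing variance);
per seed it varies by 11 % (the biology). That collapse is the point of
counting.

PBC scoring from a trait table (here the analytic table with planted
effects; `run_screen()`/`run_pipeline()` produce the same table from
images and absorbance files):

```r
tt  <- generate_trait_table(default_screen_effects())
pbc <- compute_pbc(tt$traits)
subset(pbc, conc_mM == 1 & condition == "control")[, c("compound", "pbc", "label")]
#>   compound     pbc label
#> 1 Pro      -0.0666 neutral
#> 2 Put       0.887  biostimulant
#> 3 Spd       0.682  biostimulant
#> 4 Spm      -0.941  inhibitor

classify_mode(pbc)[c(8, 12, 16, 4), ]
#>   compound conc_mM mode
#> 1 Put            1 combined
#> 2 Spd            1 growth_promotor
#> 3 Spm            1 growth_inhibitor
#> 4 Pro            1 stress_alleviator
```

`plot_parallel_coords(pbc)` and `plot_radar(pbc)` draw the standard
parallel-coordinate and radar views; `export_charts()` writes them as
CSV/JSON. A full synthetic screen (images → counts → absorbance →
growth → indices → PBC → modes) runs with:

```r
res <- run_screen(generate_screen(screen_scenario(rng_seed = 1)))
```

or, file-based with a run manifest, via `write_screen()` +
`run_pipeline("run_config.yaml")`. A thin command-line front end with
the same stages as subcommands is in `inst/cli/phenoplate.R`.

## Package layout

| Area | Functions |
|---|---|
| Layout & I/O | `plate_layout()`, `read_plate_image()`, `read_absorbance_csv()`, `read_layout_yaml()`, `write_results_table()` |
| Seed counting | `segment_seeds()`, `measure_objects()`, `count_seeds()`, `count_plate_seeds()`, `estimate_avg_seed_area()` |
| Germination | `per_seed_absorbance()`, `summarize_variant()`, `fit_germination_calibration()`, `compare_to_control()` |
| Rosette growth | `segment_rosette()`, `measure_plate_growth()`, `build_timeseries()`, `rgr()`, `establishment_area()`, `summarize_growth()` |
| Colour indices | `pixel_indices()`, `plant_indices()`, `measure_plate_indices()`, `plate_indices()` |
| PBC | `build_trait_table()`, `compute_pbc()`, `classify_mode()`, `export_charts()`, `plot_radar()` |
| Synthetic data | `seed_scan_scenario()`/`generate_seed_scan()`, `mtt_scenario()`/`generate_mtt_table()`, `growth_scenario()`/`generate_growth_images()`, `generate_trait_table()` |
| Pipeline | `screen_scenario()`, `generate_screen()`, `run_screen()`, `write_screen()`, `run_pipeline()`, `design_summary()` |

The methods vignette (`vignettes/phenoplate-methods.Rmd`) documents the
models, parameter defaults, the synthetic generator's scope, and the
design decisions in detail.
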