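---
title: "Multi-trait plate phenotyping with phenoplate: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait plate phenotyping with phenoplate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoplate)
```

phenoplate scores seed-priming treatments ("biostimulants") from two
plate assays — a tetrazolium (MTT) germination assay in 96-well plates
and a time-lapse rosette growth assay in 48-well plates — and condenses
the measured traits into a single signed score per treatment, the Plant
Biostimulant Characterization (PBC) index. This vignette explains each
model, the tunable parameters and their defaults, what the synthetic
data generator does and does not emulate, and the numerical choices made
where the design was genuinely open.

## The well coordinate system

All modules address pixels through a `plate_layout`: the pixel centre of
well A1, the centre-to-centre pitch and the well radius. Plates are
imaged in fixed positions, so a declared parametric grid is used rather
than automatic well detection — it is deterministic, testable, and the
only piece of geometry a user has to calibrate once per scanner or
camera. Channel values are normalized to $[0,1]$ on load (8-bit and
16-bit inputs map linearly), which makes every downstream colour
computation independent of bit depth.

## Seed counting by solidity

Seeds are darker than the agarose background in all three RGB channels.
Within each well the segmenter thresholds each channel (Otsu by default,
with a manual override), takes the intersection, fills holes, and drops
objects below a debris floor (default $0.25 \times$ the average seed
area). A contrast guard treats a well as empty when the Otsu split
separates means by less than 0.15 — without it, a uniform background
well would be split on sensor noise alone.

Each 8-connected component is then measured. The discriminator between
single seeds and clusters is *solidity*,

$$\mathrm{solidity} = \frac{\text{object area}}{\text{convex hull area}} \in (0, 1],$$

computed on pixel counts (hull area = pixels whose centres fall in the
convex hull of the object's pixel centres, the regionprops convention).
Single seeds are nearly convex (solidity $\approx 1$); touching seeds
form waisted unions with lower solidity. Objects at or above the
solidity threshold (default 0.9, configurable) count as one seed;
objects below it are clusters estimated as

$$n = \max\!\left(2,\ \mathrm{round}\!\left(\frac{\text{cluster area}}{\text{average seed area}}\right)\right),$$

rounding halves away from zero. The floor of 2 encodes that
sub-threshold solidity asserts multiplicity. The average seed area is
the median area of high-solidity objects pooled over the plate (at
least 10 required), or a manual value.

Two tangent circles of equal radius have solidity
$2\pi r^2 / (4r^2 + \pi r^2) \approx 0.88$ — real touching pairs sit
just below the 0.9 threshold, which is why the threshold works but also
why it should not be raised casually.

## Germination activity from dual-wavelength absorbance

Metabolically active embryos reduce MTT to formazan; its absorbance is
read at 570 nm against a 690 nm reference, and the net signal is
$A_{570} - A_{690}$. Because wells receive a variable number of seeds
(dispensing a suspension gives roughly $21 \pm 5.4$ seeds per well, a
~25 % coefficient of variation), the raw per-well signal mostly
measures seed number. Dividing by the counted seeds,

$$\text{abs/seed} = \frac{A_{570} - A_{690}}{\text{seed count}},$$

removes that variance; on simulated cohorts the CV drops severalfold,
which is the quantitative justification for counting seeds at all.

Conventions: sample (n−1) standard deviations throughout; wells with
zero counted seeds are flagged and excluded from summaries rather than
imputed; negative net absorbance (blank-level noise) is kept but only
enters summaries on request (`keep_negative`). The map from per-seed
absorbance to a germination percentage is assay-specific, so it is
exposed as a user-fit linear calibration (`fit_germination_calibration`)
with predictions clamped to $[0, 100]$; no default coefficients are
shipped.

Group comparisons are provided in two flavours because both appear in
practice for this kind of data: Kruskal–Wallis with Dunn's post hoc z
tests (default) and one-way ANOVA with pairwise contrasts via emmeans;
both use Šidák multiple-comparison adjustment
($p_{adj} = 1-(1-p)^m$). Dunn's statistic is implemented directly (with
the standard tie correction) since no installed package provides it;
the surrounding omnibus tests are base R.

## Rosette growth and RGR

Plants are segmented per well by the excess-green score $2G - R - B$
(threshold 0.10 on normalized channels), keeping the largest component
and filling holes. The relative growth rate over each imaging interval
is

$$\mathrm{RGR} = \frac{\ln A_{t_i} - \ln A_{t_{i-1}}}{t_i - t_{i-1}},$$

in pixel·pixel⁻¹·h⁻¹ (or per day, exactly $24\times$). The twice-daily
schedule (10:00 and 16:00) gives alternating 6 h and 18 h intervals;
the denominator handles the unequal spacing exactly and no resampling is
done. The per-plant summary RGR is the unweighted mean over intervals —
the simpler reading of per-day reporting; a time-weighted mean would
equal $(\ln A_{end} - \ln A_0)/T$ and is available to users as that
closed form if wanted. Because RGR is a log-ratio it is invariant to
uniform rescaling of areas (camera zoom), and on noiseless exponential
data every interval recovers the generating rate to machine precision.

Dead plants: no published rule exists, so the policy is explicit and
parameterized — a series whose green area stays below `min_alive_area`
(default 25 px) for the two or more final points is labelled dead and
truncated at the last alive point; dead plants are excluded from RGR
and growth means but counted in a reported mortality fraction.
Establishment is simply the green area at the first timepoint (the
seedling size at transfer), reported for dead plants too.

## Leaf-colour vegetation indices

Per pixel inside the plant mask:

$$\mathrm{NGRDI} = \frac{G-R}{G+R}, \qquad
\mathrm{GLI} = \frac{2G-R-B}{2G+R+B}, \qquad
\mathrm{VARI} = \frac{G-R}{G+R-B}.$$

All three are ratios, hence invariant to overall brightness. NGRDI and
GLI are bounded in $[-1,1]$; VARI is unbounded near its singularity
$G+R=B$. A pixel whose denominator is within $10^{-9}$ of zero is
excluded from that index's mean and tallied (`n_undefined_px`) — no
clipping, so the choice is transparent in the output. Aggregation
order is per-pixel index → per-plant mean → per-plate mean of plant
means; plants count equally regardless of size (a pixel-pooled mean
would weight big plants more and is deliberately not used).

## The PBC index

For each variant (compound × concentration) under each growth
condition, every trait is compared against the untreated control of the
*same* condition as $\log_2(\text{variant}/\text{control})$, and the PBC
index is the sum. Trait values are averaged over replicate wells before
the ratio (ratio of means). Under the no-salt condition four traits
contribute — germination activity (mean abs/seed), establishment (mean
time-zero area), growth capacity (mean final area of alive plants) and
colour (mean GLI); under salt stress three, because establishment is
measured before the stress is applied. Scores are therefore comparable
within a condition, not across conditions, and the radar-chart export
groups by condition.

Germination enters as the measured per-seed absorbance rather than a
calibrated percentage: the log2 ratio is invariant to any linear
zero-intercept calibration, so the index does not depend on having one.

Labels use a dead zone of $\varepsilon = 0.1$ log2 units (positive =
biostimulant, negative = inhibitor, inside = neutral); a hard
positive/negative split would flip labels on measurement noise. The
mode-of-action rule across conditions is the operationalization of
three narrative categories:

* **combined** — PBC $> \varepsilon$ both without salt and under at
  least one stress level;
* **growth promotor** — positive only without salt;
* **stress alleviator** — positive only under stress;
* **growth inhibitor** — PBC $< -\varepsilon$ without salt and no
  stress alleviation;
* **none** — everything inside the dead zone.

## The synthetic data generator

No public raw data exist for assays of this type at this scale, so the
package ships generators that emulate all three data streams with exact
ground truth; every stage and the end-to-end pipeline are tested against
them.

**Seed scans.** Seeds are filled ellipses (default semi-axes 6 × 4.2 px
in 65 px-radius wells — the same seed-to-well scale as a 1200 DPI
flatbed scan) with jittered axes and colour, placed with a separation
margin; per-well counts are drawn from the dispensing distribution
(truncated Normal(21, 5.4²), rounded). A configurable fraction of seeds
(default 10 %) attaches to an existing seed as a near-perpendicular,
tangent-distance pair: the union is either a clearly waisted two-lobed
object (exercising the solidity split) or occasionally two just-separate
seeds (still counted correctly as singles). A clearance test prevents
accidental triples, and crowded wells fall back to cluster placement as
a dense suspension would. The manifest records the exact drawn count
per well.

**MTT plates.** Each germinated seed contributes
$N(\mu_{seed}, \sigma_{seed}^2)$ OD (defaults 0.019 ± 0.002 at 24 h;
0.041 ± 0.003 at 48 h), non-germinated seeds contribute near zero; a
per-well lognormal effect (default CV 9 %) reproduces the between-well
biological dispersion seen in real per-seed summaries, and both
wavelength reads carry independent reader noise (SD 0.003).

**Growth series.** Each plant grows exponentially with a higher daytime
(10:00–16:00) than overnight rate — defaults 0.012 h⁻¹ vs 0.008 h⁻¹,
i.e. ~0.22 day⁻¹ overall, with the circadian asymmetry the assay is
sensitive to. Salt suppresses the rate (defaults ×0.7 at 75 mM, ×0.4 at
150 mM NaCl), shifts leaf colour toward yellow, and can kill plants
(the blob turns brown and shrivels, so its green area collapses).
Rosettes are rendered as lobed star-convex blobs whose pixel count
equals the rounded true area *exactly* — ground truth is the rendered
pixel count, so segmentation accuracy is judged without rasterization
slack. Planted treatment effects are per-variant multipliers on the
four traits; the colour multiplier is realized by solving the green
channel so that the rendered GLI scales exactly as planted.

What the generator does **not** emulate: leaf shape and occlusion,
uneven illumination and shadows, optics (vignetting, chromatic
aberration), condensation on plate lids, agar discoloration, and seeds
of non-elliptical outline. Passing tests therefore demonstrate that the
algorithms are correct on their stated model of the data, not that the
default thresholds are optimal for any particular scanner or camera.

## The end-to-end verification screen

`screen_scenario()` plants one unambiguous mode of action per compound
(Put combined, Spd growth promotor, Spm growth inhibitor, Pro stress
alleviator, four concentrations each, every planted PBC at least 0.3
log2 units outside the ±0.1 dead zone) and runs the full loop: scan →
counts → per-seed absorbance, images → areas → RGR and indices → trait
table → PBC → modes. Two deliberate choices:

* **Low biological noise** (initial-area CV 4 %, per-well MTT effect
  CV 2 %, no mortality): the recovery test isolates *pipeline bias*
  from biological variance. Realistic noise levels (area CV ~20 %, MTT
  well CV 9 %) are exercised separately by the CV-normalization and
  mortality tests, where variance is the point.
* **Replication**: 6 growth plates (16 wells per variant) and 2 MTT
  plates (11 wells per variant) per condition. The establishment and
  growth traits share each plant's initial-area draw, so their sampling
  errors add coherently in the index; replication, not noise reduction,
  is the honest way to bound the recovery error, and the real design
  uses 96 seedlings per variant. At these sizes the whole screen
  (48 variant × condition scores from 864 imaged plants and 576 MTT
  wells) runs in about three minutes and recovers planted indices
  within ~0.06 log2 units.

## Numerical choices and degenerate inputs

* Rounding of cluster sizes: half away from zero (base R's
  round-half-even would make $x.5$ clusters depend on parity).
* Well labels normalize `a01` → `A1`; duplicated wells, unknown
  conditions and unassigned wells are hard errors, not warnings.
* Empty segmentation masks are valid results (empty well, dead plant);
  empty *summaries* (no usable records) are errors.
* The Šidák adjustment and Dunn's z statistic are closed-form;
  ties in ranks use the standard $\sum (t^3-t)$ correction.
* All generators draw from one seeded stream per scenario; identical
  seeds give bit-identical images, tables and manifests.

## Known limitations

* The fixed-grid layout assumes the plate does not move between frames;
  a whole-grid registration offset is the natural extension if it does.
* Solidity-based splitting cannot resolve clusters whose union is
  convex (e.g. three seeds in a tight triangle); such clusters are
  counted by area ratio only if their solidity drops below threshold.
* The excess-green rule assumes green-dominant plants on a non-green
  background; strongly chlorotic (yellow-white) tissue near death is
  counted as not-green by design.
* Establishment under stress conditions is not defined (transfer
  precedes stress), so stress-condition PBC sums three traits; the
  index is not comparable across conditions with different trait
  counts.
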