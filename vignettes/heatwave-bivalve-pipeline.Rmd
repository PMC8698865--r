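---
title: "Methods: bioturbation imaging, biomarker integration and GLS selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bioturbation imaging, biomarker integration and GLS selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumibr)
```

This vignette documents the models and procedures lumibr implements, the
choices made where the methodology left room, and what the synthetic-data
generator does and does not emulate.

## The experimental frame

The package targets a two-species × two-temperature mesocosm design on
burrowing bivalves: a native and an invasive clam held in sand-filled
aquaria, with half of the animal aquaria subjected to a simulated marine
heat wave (six days at ambient 17.5 °C followed by six days at 22 °C, a
step exceeding the 90th-percentile definition of a heat wave) while the
rest stay at constant temperature (CT). `build_design()` enumerates the
default layout: per species, 4 aquaria destructively sampled at day 6
(the pre-heating baseline), 4 aquaria per species × treatment sampled at
day 12, and 4 animal-free procedural controls, for 28 aquaria in total.

Stocking densities are not part of the published record; only the totals
are (12 native and 16 invasive individuals at day 6 over 4 aquaria each,
24 and 32 at day 12 over 8 each). The densities of 3 native and 4 invasive
individuals per aquarium used here are the unique back-derivation from
those totals, and are flagged as an assumption: they matter only for how
individuals nest in aquaria, not for any per-individual statistic.

`experiment_conditions()` carries the published per-cell water-quality
summaries; `pooled_temperature()` pools them per treatment. The pooled
post-day-6 contrast (HW − CT) is just over 4 °C, which the test suite
asserts; CT aquaria sit slightly above their nominal temperature because
room heating spills over, so the realised contrast is smaller than the
nominal 4.5 °C step.

## Particle reworking from profile images

The f-SPI chain is: merge the four side photographs of an aquarium
(`merge_sides()`, side order configurable and metric-invariant, which a
property test verifies), calibrate (`pixel_scale(width_cm, width_px)`,
in µm/px; four 12-cm sides at 1349 px each give the reference 88.95 µm/px),
segment luminophores (`segment_luminophores()`), trace the sediment–water
interface (`detect_interface()`), and reduce to depth metrics
(`depth_metrics()`).

Choices that the imaging literature leaves open, and how they are fixed
here:

* **Depth reference.** Depth is measured from the interface of the pixel's
  *own column*, not from a single horizontal line; a sloping or rough
  surface otherwise biases every metric. Pixels above the interface are
  floored to depth 0 — they are optical artefacts (grains stuck to the
  glass, reflections), not negative reworking.
* **Segmentation.** The published analyses used an ImageJ plugin whose
  threshold is not public. lumibr thresholds in HSV space: hue within an
  orange band (default 15–55°), saturation and value above minima (0.4).
  The defaults match the generator's luminophore colour; for real imagery
  they are tuning parameters.
* **Interface tracing.** Sediment is distinguished from the overlying
  water by Rec.709 luminance (default threshold 0.15, sediment bright
  against the dark water column of a UV photograph; direction
  configurable). A column's surface is the first run of at least 5
  consecutive sediment pixels — the run requirement rejects isolated
  speckle — and elevations are smoothed by a running median over 11
  columns (~1 mm at full resolution). Columns with no detectable sediment
  are excluded from roughness and reported.
* **Median convention.** `L_median` over an even pixel count is the
  midpoint of the two central values (the R default).
* **SBR aggregation.** Surface boundary roughness is the interface range
  per side, averaged over the four sides of the aquarium
  (`aggregate_sbr()`).

On noise-free synthetic images the whole chain is *exact*: the segmented
mask equals the truth mask pixel for pixel, and unsmoothed interface
detection recovers the true elevations, so estimated metrics equal
truth-mask metrics identically. The acceptance tests assert this, plus
Monte-Carlo agreement with the analytic moments of the seeded burial law
(mean within 3 MC standard errors, maximum within one pixel) and exact
roughness recovery for step interfaces.

## The synthetic image generator

`render_fspi_image()` draws a dark water column over a grey-blue sediment
body, places luminophore pixels at depths drawn from a configurable law
below a configurable interface shape, and returns the exact label mask and
interface — ground truth for scoring. Burial laws: `surface` (unreworked),
`uniform(0, d)`, `exponential(mean)` with optional truncation at the
sediment-column depth (particles cannot be mixed below the aquarium
floor), and `point(d)` for exact oracles. Interface shapes: flat, step
(exact roughness `|h1 − h2|`), sinusoid, each with optional per-column
pixel jitter. Noise dials (default off): salt-and-pepper speckle and
Gaussian luminance jitter, used by the segmentation-robustness test
(pixelwise F1 ≥ 0.95 at speckle probability 0.002 and luminance SD 0.03).

The generator emulates *geometry and colour*, not sediment optics: no
grain texture, no luminophore size distribution (one particle = one
pixel), no lighting gradients, no lens distortion, no burial-activity
dynamics (it draws from a depth law rather than simulating animals).
Passing its tests therefore demonstrates that the measurement chain is
correct and well-calibrated on images whose truth is known — not that the
segmentation thresholds transfer to any particular camera set-up.

In the end-to-end pipeline the species contrast is emulated by giving the
native species a truncated-exponential burial law with mean 0.96 cm
(median/mean ≈ 0.7, matching the reported profile shape) and the denser
invasive species a uniform law to 4.26 cm (mean 2.13 cm, median ≈ mean,
as reported); controls are surface-only. The pipeline default resolution
(150 px per 12-cm side, i.e. 800 µm/px, 160 px tall) keeps a 20-aquarium
imaging run to a few seconds; the full-resolution geometry is one config
change and alters nothing structurally.

## Biomarker normalization and the energy budget

Raw biomarker values are only comparable within a species and assay, so
all responses are expressed as percent change from the species' day-6
baseline mean (`normalize_biomarkers()`):
\[ B^n_{i,j} = \frac{B^{D12}_{i,j} - \bar{B}^{D6}_i}{\bar{B}^{D6}_i} \times 100. \]
The transformation is unit-free and scale-invariant (rescaling a
biomarker's units leaves every normalized value unchanged — a property
test), and units are therefore carried as opaque labels; only consistency
within a biomarker matters.

The energy budget is derived per individual *before* any averaging, so
that `Ea` and `CEA` flow into normalization and the IBR index exactly like
assayed biomarkers: `Ea = protein + carbohydrate + lipid` (a common energy
unit is assumed — the ratio is computed on values as provided) and
`CEA = Ea / Ec` with `Ec` the ETS activity.

`change_summary()` reports two standard errors for each cell's mean
change. The conventional SE (dispersion of the day-12 individuals alone,
`se_naive`) understates the uncertainty of the *mean* change because every
normalized value shares one estimated baseline mean; when baseline and
final-day cells are the same size, a naive interval's asymptotic coverage
drops to roughly 83 %. The delta-method SE (`se_change`) adds the baseline
term \((100\, m_{12} / m_6^2)^2 s_6^2 / n_6\), and the confidence interval
uses it with a t quantile on `min(n_D6, n_D12) − 1` degrees of freedom —
deliberately slightly conservative at these cell sizes (12–16). The
parameter-recovery acceptance test uses this interval: over 200 replicate
panels the intervals cover the generating effect sizes at close to the
nominal rate, which a naive interval would fail.

## The synthetic biomarker generator

`sample_biomarkers()` draws `value = baseline × multiplier × noise` per
individual and biomarker, with unit-mean lognormal noise (so expected
values are exactly `baseline × multiplier`), identical noise law on both
days, and the multiplier applied only at day 12. `default_effect_spec()`
fixes the study conditions once:

* **Multipliers** are 1 + (reported % change)/100 for every species ×
  treatment cell with a published value (e.g. DNA damage ×3.06 in the
  native species; ETS ×0.62 for the invasive under HW; lipid ×1.65 for
  the invasive under HW). Where only a species-level change was published
  (CAT for the invasive, DNAd, IDH, protein) both treatment cells share
  it; biomarkers with no published change (SOD, LDH) keep multiplier 1.
* **CVs** (0.2–0.6 per biomarker) were back-converted once from the
  published standard errors via SD = SE·√n and rounded; they are
  between-individual CVs, identical across days and species.
* **Baselines** are round, plausible assay values; their absolute levels
  cancel from every normalized statistic.

Because the noise law is identical on both days, the multiplicative bias
of the per-individual CEA ratio (E[1/ETS] exceeds 1/E[ETS] by 1 + CV²)
cancels from the normalized change, and the expected CEA change is the
ratio of the component multipliers. Note a consequence: the published
per-component changes for the invasive species under HW compose to a CEA
multiplier near 1.87 under independent noise, not the published +63 % —
in the real data reserves and consumption were correlated within
individuals, which the generator does not emulate. The CEA recovery check
therefore uses the calibration in which the three reserves are scaled by
×1.63 with ETS unchanged, making the generating CEA change exactly +63 %.
The generator also does not emulate aquarium-level nesting (individuals
are independent given their cell), assay detection limits, or
non-lognormal outliers.

## The IBRv2 index

`ibr_v2()` implements the reference-deviation index in four steps, each
exported for testing: log ratio `Y = log10(B_D12 / B̄_D6)`; standardization
`Z = (Y − µ)/s` with µ and s computed per biomarker *within species ×
treatment* (sample SD, n−1); the day-6 reference term
`Z_D6 = mean(log10(B_D6 / B̄_D6))`, taken literally as the unstandardized
mean log ratio; the deviation index `A = Z − Z_D6`; and
`IBRv2 = Σ_b |A_b|` per individual, summarized as mean ± SE over
individuals per condition.

Where the index's description is ambiguous, the defaults are:

* **Grouping of µ and s.** "General mean" could mean per condition or per
  species pooled over treatments. The per-condition reading matches
  per-condition index reporting and is the default; `grouping = "species"`
  selects the pooled alternative.
* **Log base.** Base 10, following the original formulation, exposed as
  `log_base`. The standardized `Z` is base-invariant (the base cancels in
  (Y − µ)/s); the unstandardized reference term `Z_D6` scales with the
  base, so the index is base-sensitive only through it. A dedicated test
  asserts both behaviours.
* **Aggregation.** The index is computed per individual and then averaged
  (mean ± SE), matching how condition-level values with standard errors
  and statistical tests on the index are reported; the alternative of
  computing one index from cell means would preclude both.
* **Zero variance.** A biomarker with no spread in a cell cannot be
  standardized; by default (`zero_variance_guard = TRUE`) its deviation
  contribution is set to 0 with a warning instead of failing, so
  degenerate synthetic cells cannot crash a run. Jensen's inequality makes
  `Z_D6` non-positive; a single day-6 individual gives `Z_D6 = 0` exactly.

The implementation is verified against a straight-line oracle — a loop
re-implementation of the four steps with no grouping machinery — to
1e-12 on 100 random panels, and `star_plot_data()` /
`autoplot()` decompose the index into the fixed seven-axis star plot
(SOD, CAT, DNAd, LPO, IDH, LDH, CEA — CEA enters the integrated set as a
derived biomarker).

## GLS model selection

The minimal-adequate-model workflow is: (1) fit the full species ×
treatment factorial; (2) extend it with a variance covariate (separate
residual variance per species, per treatment, or per cell, via
`nlme::varIdent`) and keep the extension only if it lowers REML AIC
against the homoscedastic baseline, ties going to fewer parameters
(`select_variance_structure()`); candidates whose fit degenerates (e.g. a
zero-variance stratum) are recorded as NA and skipped; (3) prune fixed
terms by backward selection under ML likelihood-ratio tests at α = 0.05,
never dropping a main effect while its interaction survives
(`backward_select()`); (4) re-express the surviving model with REML.
Estimation is delegated to nlme — the same engine such analyses
standardly use — while the package owns the workflow, bookkeeping
(`AIC = −2 logLik + 2k` with k counting fixed coefficients, variance
parameters and the residual SD) and reporting. LR degrees of freedom are
reported as the parameter-count difference between the compared models,
matching the `df = 2` convention of factor tests in this literature.

Calibration, asserted by the acceptance tests at fixed seeds: the LR test
of a 2-parameter reduction holds its size (empirical type-I in
[0.03, 0.07] at α = 0.05 over 2000 null simulations, 25 replicates per
cell — a moderate size where the chi-square reference is accurate); with
strong per-species heteroscedasticity (SD ratio 3, 50 per cell) the
species structure is selected in at least 80 % of 200 replicates. Note a
structural ceiling: with four candidate structures screened
simultaneously, richer structures win by chance in roughly 14 % of
homoscedastic datasets, so "keep identity when the data are homoscedastic
at least 80 % of the time" holds for the screen against the no-structure
baseline (the comparison the workflow describes), and the corresponding
test screens identity against one alternative.

Procedural-control aquaria are removed before ecological-response fits
(`drop_procedural_controls()`): the contrasts of interest are between
species, not presence versus absence.

## Pipeline, reproducibility and problem sizes

`run_pipeline()` chains generator → imaging → normalization/CEA → IBRv2 →
model selection from a single nested configuration (R list or YAML), with
all randomness flowing from one master seed, and writes per-stage CSVs, a
JSON model report, QC-ready images and a manifest with per-file MD5
checksums. Identical configuration and seed give byte-identical outputs
(asserted). A missing required configuration key fails validation naming
the key.

Problem sizes were chosen so a complete run stays interactive: pipeline
images at 150 px/side (a 20-aquarium imaging run in seconds),
Monte-Carlo suites at 200 replicate panels, 2000 null simulations for the
LR size check, and oracle suites of 100 random panels. All are
configuration or test constants, and the full-resolution image geometry
(1349 px/side) is supported unchanged.

## Known limitations

* The generator's independence assumptions (individuals within aquaria,
  biomarkers within individuals, reserves vs consumption) are simpler
  than real data; aquarium-level random effects are out of scope, and the
  GLS models accordingly treat individuals as independent units.
* Segmentation thresholds are validated against the generator's colour
  model only; real imagery requires recalibration and the QC overlay
  (`overlay_qc()`) exists for exactly that.
* Published group values that are not recomputable from published inputs
  (absolute biomarker levels, exact L-ratios of the original fits) are
  outside what the package can or attempts to reproduce; the acceptance
  machinery targets the recomputable set and the calibration properties.
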