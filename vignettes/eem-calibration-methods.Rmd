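---
title: "Multivariate calibration of overlapping fluorophores from EEM landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate calibration of overlapping fluorophores from EEM landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eemcal)
```

## The problem

An excitation–emission matrix (EEM) records fluorescence intensity at every
pair of excitation and emission wavelengths for one sample — here a 41 × 41
landscape on a 200–600 nm grid with 10 nm steps on both monochromators.
When two fluorophores have strongly overlapping spectra (the motivating
case is a pair of coumarins, a glycoside and its aglycone, whose emission
bands nearly coincide), no single wavelength pair is selective for either
compound and univariate quantification fails. Multivariate calibration
recovers the concentrations by using the whole landscape, or a structured
reduction of it, together with a set of standards of known composition.

`eemcal` implements three calibration engines over a common preprocessing
chain, plus the cross-validation statistics used to pick their complexity,
the validation statistics used to compare them, and a synthetic-data
generator that emulates the study design the methods assume.

## Data model

A `wavelength_grid` holds the two axes; an `eem_landscape` is one sample's
emission × excitation intensity matrix; an `eem_dataset` stacks samples
into a three-way cube indexed (sample, emission, excitation) and aligns it
with a concentration table in µg/ml. The cube orientation is sample-major
so that cross-validation folds and calibration splits are contiguous
slices. On disk, one CSV per landscape (excitation wavelengths across the
header row, emission wavelengths down the first column, `em\ex` in the
corner) plus one concentration manifest.

## Synthetic data generator

No measured spectra are distributed with the package, so every test and
the acceptance study run on synthetic data whose structure mirrors the
assumed physics:

* **Trilinear signal.** Each analyte contributes
  `c · s · em-profile ⊗ ex-profile`; profiles are single Gaussians with
  unit maximum, and `s` (sensitivity) carries the intensity scale. The
  defaults — analyte A: emission 340/35 nm, excitation 300/30 nm,
  sensitivity 1000; analyte B: emission 360/40 nm, excitation 310/35 nm,
  sensitivity 250 — give emission profiles correlated above 0.9, the
  overlap regime the methods exist for, and comparable maximum signals at
  the tops of the two concentration ranges.
* **Concentration design.** 21 mixed standards by default; per-analyte
  concentrations drawn independently and log-uniformly over
  0.002–1.020 µg/ml (A) and 0.009–4.000 µg/ml (B). Log-uniform because the
  ranges span nearly three orders of magnitude and a uniform draw would
  leave the low decades empty.
* **Scatter.** Gaussian ridges along the first-order Rayleigh line
  (λ_em = λ_ex), the second-order line (λ_em = 2 λ_ex), and the solvent
  Raman line at a 3400 cm⁻¹ shift from the excitation. Amplitudes default
  to 50% (both Rayleigh orders) and 5% (Raman) of the design's maximum
  clean signal; the ridge cross-section sigma defaults to 5 nm, a
  realistic monochromator bandwidth. Scatter is concentration-independent,
  so dilute samples genuinely have poor scatter-to-signal ratios.
* **Noise.** Additive i.i.d. Gaussian, sd = 1% of the design's maximum
  clean signal by default. The noise scale is a design-level constant
  rather than per-sample, again so dilute samples are noisier in relative
  terms.
* **Spiked pairs.** Real-sample surrogates for recovery studies come in
  unspiked/spiked pairs: the spiked member has exactly `base + spike`
  with default spikes of 0.48 µg/ml (A) and 2.00 µg/ml (B), the magnitudes
  typical of spike-recovery protocols at these concentration ranges.

All randomness flows from one integer seed; regenerating a design is
bit-stable. What the generator does **not** emulate: inner-filter effects,
quenching, pH dependence, instrument drift, and uncalibrated background
fluorophores (an interferent hook exists but is off by default). Passing
tests therefore demonstrate correctness of the algorithms under the
trilinear-plus-scatter model, not robustness to every pathology of real
extracts.

## Preprocessing

**Scatter excision.** `build_scatter_mask()` marks cells within
half-widths `w1`, `w2`, `wR` (defaults 15, 15, 10 nm) of the three ridge
lines. Width zero keeps exactly the on-grid ridge cells.

**Infilling.** `excise_and_interpolate()` replaces masked cells with a
natural cubic spline along the emission axis through each column's
unmasked cells, held constant beyond the outermost anchors. A spline
rather than straight-line segments because the Raman band cuts directly
across the emission apex of the default analytes: linear infill
under-estimates any curved band by its full sagitta (8–13% of peak on the
default design), while the spline tracks curvature and restores the known
clean landscape to within about 4% of peak at the reference mixture
(0.16/1.0 µg/ml). Both rules are exact on affine surfaces; only reading
unmasked cells makes the operation exactly idempotent.

**Non-fluorescent triangle.** Cells with λ_em < λ_ex cannot contain Stokes
fluorescence; `zero_nonfluorescent()` zeroes them outside the masked bands.
This is kept as a separate step (applied by `preprocess_dataset()` after
infilling) rather than folded into the excision: zeroing first would turn
the below-diagonal cells into zero-valued interpolation anchors and bias
every near-diagonal infill downward by tens of percent.

**Known limitation.** For dilute samples the concentration-independent
scatter dominates the signal and the restored landscape can deviate by
more than 5% of its own (small) peak; this is a property of the
measurement physics being emulated, not of the infill rule.

**Contour extraction.** The LAR and iPLS engines work on contour vectors:
the 41 emission intensities at one fixed excitation. The default policy
picks the excitation column with the largest summed intensity over the
calibration samples only (no information from held-out samples), and every
sample then uses that same column; a fixed-wavelength policy is also
provided since the choice is not uniquely determined by the original
protocol.

**Calibration split.** `split_calibration()` takes
round-half-up(fraction · n) samples for calibration (21 samples at 3/4
give the conventional 16/5), clamped to leave at least one sample on each
side. Selection is deterministic and concentration-stratified: samples are
ranked by the target analyte and every ⌊n/n_pred⌋-th rank is held out, so
the prediction set spans the whole range.

## Model selection statistics

Leave-one-out cross-validation is used throughout: sample *i* is predicted
by a model fitted without it, and

* `RMSECV = sqrt( Σ (yᵢ − ỹᵢ)² / m )`
* `PRESS  = Σ (yᵢ − ŷᵢ)²  =  m · RMSECV²`

Leave-one-out (rather than k-fold) because the calibration sets here are
small (m = 16) and LOO is the scheme the interval-selection procedure is
defined with; PRESS uses the same folds for consistency.

## The three engines

### Lasso on contour values (LAR)

`lar_fit()` solves `min (1/2m)‖y − β₀ − Xβ‖² + λ‖β‖₁` by cyclic
coordinate descent with Gram-matrix updates (compiled kernel), on
predictors standardized to zero mean and unit population sd with the
coefficients back-transformed, so the reported model is the sparse affine
equation `C = β₀ + Σ_λ β(λ) V_λ` on raw intensities. Convergence is
declared when a full sweep changes no coefficient by more than 1e-10 or
the duality gap falls below 1e-8 of the null objective; the subgradient
conditions of returned fits are verified in the tests. `select_penalty()`
evaluates a 30-point log grid from λ_max (the smallest penalty that zeroes
everything) down four decades by LOO RMSECV, with warm starts along the
path, and returns the minimizer; ties go to the sparser model. Predicted
concentrations are not clipped at zero — recovery arithmetic needs the raw
values — but negative predictions carry a flag.

A note on a tempting "invariant": the number of selected wavelengths is
*not* monotone in the penalty for correlated designs (the lasso path drops
and re-adds variables); it is provably monotone for orthonormal designs,
where the solution is coordinate-wise soft-thresholding, and that is where
the property is tested.

### Interval PLS (iPLS)

`make_intervals()` splits the 41 contour variables into 8 contiguous
intervals (seven of width 5, the remainder to the last). For every
interval and every admissible component count (capped by interval width,
m − 2, and `max_components = 10`), a local PLS1 model (NIPALS on centered
data) is scored by LOO RMSECV; `ipls_select()` returns the exact argmin of
that table, breaking ties toward fewer components and then the lower
interval index (parsimony before position). The full RMSECV table is kept
on the model object and is checked against a brute-force recomputation in
the tests.

### Trilinear N-PLS (tri-PLS1)

`npls_fit()` operates on the centered cube (mean slab subtracted; no
scaling, which second-order calibration practice avoids and the centering
identities require). Per latent variable: the emission/excitation weight
pair is the leading singular pair of `Z = Σᵢ y_res,i · X_res,i`; scores are
the cube's projections on the rank-1 weight matrix; y is regressed on all
scores accumulated so far; cube and response are deflated. The SVD sign
ambiguity is fixed by making each emission weight's largest-magnitude
element positive (the paired excitation weight flips with it, leaving the
fit unchanged), so results are bitwise reproducible.
`select_lv_by_press()` runs LOO, evaluating every truncation of a single
`max_lv`-factor fit per fold, and takes the PRESS minimum. Two numerical
choices matter:

* minima are compared with a 1e-9 relative tie tolerance, taking the
  fewest latent variables among indistinguishable values — on noiseless
  data the curve is flat at machine zero beyond the chemical rank and a
  strict argmin would return an arbitrary overfitted count;
* a first-local-minimum rule is available (`rule = "local"`) for curves
  that keep creeping downward with overfitted factors.

On the default noiseless two-analyte design, two latent variables predict
held-out concentrations to within 1e-6 relative; with 1% noise and
scatter, spike recoveries on surrogate pairs concentrate tightly around
100%.

## Validation

`evaluate_model()` reports Pearson correlations (Rc, Rp) and root mean
squared errors (RMSEC, RMSEP) for the calibration and prediction sets,
with the m-denominator (no degrees-of-freedom correction) so RMSEC applied
to cross-validated predictions coincides with RMSECV. Replicate
measurements of one physical sample are averaged on the
predicted-concentration scale. Spike recovery is
`100 · (Con₁ − Con₀)/Con_s` — spiked minus unspiked prediction over the
known added amount — reported unclipped. `compare_methods()` assembles the
long-format method × analyte × statistic table and the recovery table.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → preprocess → split → contours →
fit (all three engines, each with its own model selection) → validate →
report from one configuration list (or YAML file), writing CSV/JSON
artifacts with 12-significant-digit formatting. Each stage derives its own
child seed from the global seed and the stage name, so adding a stage
never perturbs earlier stages' randomness; reruns with the same seed are
byte-identical. The default study — 21 standards, 1% noise, scatter on,
6 spiked pairs, 16/5 split — completes in well under a minute on one CPU;
the test suite scales its repetition counts (200 recovery repetitions, a
1000-trial identity check) to stay fast while still exercising the
distributional claims.

## Design choices that were genuinely open

* **Contour policy.** The dimensionality-reduction step is described in
  the source literature only as "fixing the excitation wavelength"; both a
  fixed-wavelength and a maximum-energy policy are provided, the latter as
  default with the column chosen on calibration data only.
* **Interval boundaries.** 41 variables cannot form 8 equal intervals;
  the remainder goes to the last interval. Boundaries are configurable
  via the scheme object.
* **PRESS folds.** The fold scheme for PRESS-based selection is not fixed
  by the formula; LOO is used to match the RMSECV machinery.
* **Standardization before the lasso.** Internal standardization with
  back-transformation was chosen so that reported coefficients live on the
  raw intensity scale of the contour values.
* **Splitting rule.** Which samples were held out in the original design
  is unknowable; the rank-stratified systematic rule here is deterministic
  and spans the concentration range, which is what a 16/5 split is for.

## Limitations

The synthetic benchmark demonstrates algorithmic correctness, not
real-extract performance: real samples add background fluorophores,
inner-filter curvature at high absorbance, and replicate-level measurement
drift that the generator does not model. The N-PLS engine is single-
response (tri-PLS1); multi-response N-PLS2 and PARAFAC-style decompositions
are out of scope, as is any handling of missing cells inside the cube
(infilling happens in preprocessing).
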