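---
title: "memfluor: models, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{memfluor: models, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfluor)
```

`memfluor` implements the fluorescence-based analysis chain used to
characterise how small ligands interact with lipid membranes, erythrocytes
and a carrier protein. This vignette is the package's own account of the
underlying models, the tunable parameters, the numerical decisions taken
where the methods literature leaves them open, and what the synthetic-data
round trips do and do not demonstrate.

## Spectral preprocessing

Emission spectra live on a strictly increasing, uniform wavelength grid
(tolerance 1e-9 nm; the canonical acquisition is 310–500 nm in 1 nm steps
with 295 nm excitation). Three operations mirror the standard acquisition
chain:

* `average_scans()` — pointwise mean of repeated scans; scan counts
  accumulate in `n_scans_averaged`.
* `subtract_background()` — pointwise blank subtraction. Negative results
  are **kept and flagged**, never clipped: clipping would bias every
  downstream `F/F0` ratio upward near zero signal.
* `smooth_moving_average()` — centred moving mean, default window 5 (the
  usual spectrofluorimeter setting). At the edges the window **shrinks
  symmetrically** (radius `min(h, i-1, n-i)`), so edge points are averaged
  over fewer but still centred neighbours; this keeps the operator linear
  and leaves a constant spectrum exactly invariant.

Grids must match exactly across spectra; no silent resampling is performed,
because interpolation would hide acquisition errors. The order of
operations in the pipeline is background subtraction, then averaging, then
smoothing; the applied smoothing is recorded in the titration's
`preprocessing` field. `peak_emission()` is a plain argmax with ties broken
toward the lower wavelength and a degenerate-peak warning for all-equal
spectra.

## Membrane probe metrics

Anisotropy `A = (I∥ − G·I⊥)/(I∥ + 2·G·I⊥)` and generalized polarization
`GP = (I440 − I490)/(I440 + I490)` are dimensionless intensity ratios,
invariant under common rescaling of both channels. `A` is range-checked
against the one-photon physical bounds [−0.5, 1]; out-of-range values raise
a data-quality warning rather than an error, since slightly out-of-range
values are a recognisable calibration symptom, not a computational failure.
The apparatus constant `G` is accepted **per reading**: whether `G` is
measured per sample or per session is instrument practice, and carrying it
with each reading covers both. Probe context (2.5 µM probe, 100:1
lipid-to-probe, 37 °C) is metadata only.

Dose–response tables summarise replicates as mean ± sample SD per
(treatment, concentration) cell, typically at compound concentrations of
5–30 µM with three replicates and a DMSO control.

## Dunnett many-to-one comparisons

All treated-vs-control significance flags use the Dunnett procedure at the
conventional α = 0.05 (`*`) and α = 0.01 (`**`). The joint null of the
comparison t statistics is multivariate t with the product correlation
structure `ρij = √(ninj/((ni+n0)(nj+n0)))`; adjusted p-values and critical
constants are computed from that distribution with `mvtnorm` (quasi-Monte
Carlo under a fixed internal seed, absolute tolerance 1e-5, so repeated
analyses of the same data are reproducible to well below any reporting
precision). This exact computation was preferred over Monte-Carlo-estimated
critical constants: it is more accurate at equal cost and reduces to the
pooled two-sample t-test exactly when there is a single comparison.
`simulate_dunnett_fwer()` provides the calibration check: under the global
null the familywise error matches α within Monte-Carlo error (the test
suite runs k = 4, n = 3, 10,000 replicates per α — the typical
dose-response design).

## Hemolysis and osmotic fragility

Percent hemolysis is `100·A540(sample)/A540(total)`, clamped to [0, 100]
with an out-of-range flag; fragility data tolerate ±2 percentage points of
assay noise outside [0, 100] (clamped, flagged) and reject anything worse.

Fragility curves (hemolysis vs NaCl % w/v, typically 0.5–0.9% in 0.05
steps) are summarised by a two-parameter decreasing logistic
`H(c) = 100/(1 + exp((c − c50)/s))`, `s > 0`, fitted by nonlinear least
squares (`minpack.lm::nlsLM`, started from the interpolated 50% crossing).
The assay itself only compares curves visually; `c50` is added as the
standard fragility index because it turns "shifted left/right" into a
number. Identifiability requires at least four NaCl levels spanning both
plateaus (<20% and >80% mean hemolysis); otherwise the fit aborts rather
than extrapolate.

`compare_resistance()` tests each matched NaCl level two-sidedly (the
Dunnett machinery; pooled t-test in the two-group case) and classifies the
overall shift from the sign of `c50(treated) − c50(control)` **only when
some level is significant**; otherwise the result is `unchanged` regardless
of the c50 sign, mirroring the visual-plus-test logic of the assay. The
classification is antisymmetric under exchanging the curves.

## Erythrocyte morphology

Counts over the eight Bessis–Brecher categories (D, SS, S, DS, DE, E, SE,
ES; ~500 cells per replicate) become percentage shares that sum to 100 per
replicate. Treated-vs-control comparison is per category on
arcsine-square-root-transformed shares — the classical variance-stabilising
transform for proportions; the raw-share comparison stays available via
`transform = "none"`. Categories below a 2% share in both groups are still
tested but marked `rare` and collapsed into an "other" row by the print
method, matching how such populations are reported. All eight categories
are retained in the data model; which ones are negligible is left to the
data.

## Quenching and binding analysis

The titration model is the accessible-fraction (modified Stern–Volmer)
law. In its linearised form `F0/(F0 − F) = 1/(fa·KSV·[Q]) + 1/fa`, an
ordinary regression of `y = F0/(F0−F)` on `x = 1/[Q]` yields
`fa = 1/intercept` and `KSV = intercept/slope`. Units are mol/L internally
(concentrations accepted in µM, τ0 in ns), with constants reported in M⁻¹
and M⁻¹s⁻¹. The Q = 0 point supplies `F0` only — both transforms are
undefined there — and points with `F ≥ F0` are excluded with a reported
count (`n_points_used` makes the effective regression size explicit, since
exclusion counts are rarely reported). `Kq = KSV/τ0` holds exactly by
construction (default τ0 = 2.5 ns, the tryptophan lifetime of serum
transferrin), and the mechanism is `static` strictly above the
diffusion-limited bound 2×10¹⁰ M⁻¹s⁻¹ — a value exactly at the bound is
classified `dynamic`, the conservative convention for a threshold that is
itself an upper bound for collisional quenching.

### Weighting of the transformed fits

Under the multiplicative intensity-noise model `F ~ F·(1 + ε)`,
`σ(y)/y ≈ (F/(F0−F))·σ(ε)` by the delta method: the least-quenched point of
a 5–50 µM titration carries roughly eight times the relative ordinate error
of the most-quenched one, *and* the largest leverage (`x = 1/Q`). Plain
unweighted regression on the transformed variables is therefore very
inefficient — simulation in the test suite shows median `KSV` errors of
order 20% at 1% per-scan noise. The default fits consequently apply
inverse-variance weights derived from the same noise model
(`w = (F0/(y²F))²` for Stern–Volmer, `w = ((F0−F)/F0)²` for the double-log
fit); `weights = "none"` reproduces the plain graphical regression. At zero
noise the weighted, unweighted and direct nonlinear fits agree to numerical
precision (the suite asserts relative 1e-6 against
`stern_volmer_fit_nls()`, an independent `nlsLM` route kept as a
cross-check, not the default). The reported `R` remains the Pearson
correlation of the *unweighted* transformed scatter, matching how such
plots are conventionally annotated.

### Scatchard sensitivity

The double-log fit `log10(F0/F − 1) = log10(Ka) + n·log10[Q]` estimates `n`
as a slope over about one decade of `[Q]`, but `Ka = 10^intercept`
extrapolates that line to `[Q] = 1` M — ~4.7 decades outside a micromolar
titration. A slope error δn therefore multiplies into a relative `Ka` error
of roughly `ln(10)·4.7·δn ≈ 11·δn`. Even near-efficient estimates at the
protocol noise level leave per-titration `Ka` scatter of order 10%, an
information limit of the double-log parameterisation rather than an
implementation artefact. The acceptance checks therefore require exact
`n = 1`, `Ka = KSV` agreement at zero noise (closed form: for `fa = 1`,
`F0/F − 1 = KSV·[Q]`), per-titration `n` within [0.95, 1.05], and
median-level agreement of `Ka` with `KSV` across 100 simulated titrations.

### Corrections that default to off

Dilution correction (`(V0 + Vadded)/V0` on intensities) and inner-filter
correction (`F·10^((Aex+Aem)/2)`) are implemented but off by default: in
the manual micro-titration protocol emulated here both effects are small
and conventionally folded into measurement error. `absorption_ratio_check()`
gates a warning instead — a protein-to-compound molar absorption ratio
below 10 at the excitation wavelength flags possible inner-filter
contamination. `detect_emission_shift()` reports the maximum displacement
of the emission peak along the titration (tolerance 2 nm, twice the grid
step); its absence supports pure proximity quenching without
conformational change.

## Synthetic data: what it emulates, and what it does not

Each generator inverts its analysis exactly at zero noise, which is the
backbone of the test suite:

* `simulate_titration()` renders `F(Q) = F0·[(1−fa) + fa/(1+KSV·Q)]` as
  Gaussian emission bands (centre 328 nm, SD 25 nm) on the 310–500 nm grid.
  The band is Gaussian because only the band position is physically pinned;
  the width was set so the band fills the recorded window like a real
  tryptophan emission. Each spectrum is the average of `n_scans = 3` raw
  scans with 1% multiplicative per-point noise — the documented acquisition
  convention — and the analysis chain applies the 5-point smoothing via
  `smooth_titration()`.
* `simulate_polarized()` / `simulate_gp()` invert the anisotropy and GP
  definitions for a chosen true value and total intensity.
* `simulate_fragility()` draws the logistic law with additive noise
  (default 2 percentage points) on the 0.5–0.9% NaCl grid, three
  replicates.
* `simulate_morphology()` draws multinomial counts (~500 cells, three
  replicates); the default control population is predominantly discocytes
  with a small echinocytic tail and <2% of the remaining forms.

Noise defaults (1% multiplicative for intensities, 2 points additive for
hemolysis) keep recovery tests sensitive but stable and are all
overridable. All generators accept a seed, restore the caller's RNG state,
and the pipeline derives independent per-stage streams from one top-level
seed.

What passing these round trips does **not** show: the generators produce
single Gaussian bands without scattering, photobleaching, instrument
response, baseline drift or correlated (lamp-fluctuation) noise; fragility
noise is homoscedastic while real plateau noise is not; morphology counts
assume perfect classification. Recovery performance on real spectra
therefore bounds from above, not equals, the simulated performance.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use 100 seeded titrations for the
binding-recovery checks, 10,000 null replicates per α for the Dunnett
calibration, 200 curves for the C50 bias check and 400 two-table draws for
the morphology null rate — sizes chosen so each stochastic check has
Monte-Carlo error comfortably below the band it asserts. Every stochastic
quantity in the acceptance script flows from the `--seed` argument.

## Known limitations

* Time-resolved anisotropy, order-parameter conversion, FRET distances and
  thermodynamic (van 't Hoff) analysis are out of scope.
* The Stern–Volmer machinery assumes a single fluorophore class and a
  single quenching mechanism (linear transformed plots); curvature is not
  modelled, only exposed via the reported correlation.
* `Ka` from the double-log fit carries the extrapolation sensitivity
  discussed above; confidence statements about `Ka` should come from the
  titration design, not from the plot's correlation coefficient.
* The Dunnett adjusted p-values rely on quasi-Monte-Carlo integration;
  they are reproducible under the fixed internal seed but carry ~1e-5
  absolute integration error — irrelevant at reporting precision, worth
  knowing at p ≈ α boundaries.
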