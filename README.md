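# memfluor

Fluorescence analytics for membrane biophysics and protein–ligand binding
studies, in R.

Small-molecule ligands (flavonoids and their glycosides are the motivating
case) are routinely characterised by a chain of fluorescence assays: membrane
probes report how a compound changes lipid order and fluidity, hemolysis and
osmotic-fragility curves report erythrocyte toxicity and membrane
stabilisation, shape-category counts report where in the bilayer the compound
sits, and tryptophan-quenching titrations of a carrier protein
(e.g. holo-transferrin) report binding affinity and mechanism. `memfluor`
implements that chain as a tested, reusable package: spectral preprocessing,
the probe metrics, the fragility and morphology statistics, the
Stern–Volmer/Scatchard binding analysis, and seedable synthetic-data
generators whose forward models invert exactly under each analysis at zero
noise.

## The core quantities

* **DPH fluorescence anisotropy** (hydrocarbon-chain region; higher A =
  lower fluidity):
  `A = (I∥ − G·I⊥) / (I∥ + 2·G·I⊥)`, with `G` the apparatus constant.
* **Laurdan generalized polarization** (head-group packing/hydration):
  `GP = (I440 − I490) / (I440 + I490)`.
* **Percent hemolysis**: `100 · A540(sample) / A540(total lysis)`, and the
  **osmotic-fragility curve** summarised by a decreasing logistic
  `H(c) = 100 / (1 + exp((c − c50)/s))` whose `c50` (% NaCl at 50%
  hemolysis) is the fragility index; a left shift means higher osmotic
  resistance.
* **Modified (accessible-fraction) Stern–Volmer quenching**:
  `F0/(F0 − F) = 1/(fa·KSV·[Q]) + 1/fa`, giving the quenching constant
  `KSV` (M⁻¹) and accessible fraction `fa`; the bimolecular rate constant
  `Kq = KSV/τ0` classifies the mechanism as static when it exceeds the
  diffusion-limited bound 2×10¹⁰ M⁻¹s⁻¹.
* **Scatchard double-log binding fit**:
  `log10(F0/F − 1) = log10(Ka) + n·log10[Q]`, giving the binding constant
  `Ka` (M⁻¹) and binding-site number `n`.
* **Dunnett many-to-one comparison** with familywise error control
  (exact multivariate-t, via `mvtnorm`) backs every treated-vs-control
  significance flag (`*` at α = 0.05, `**` at α = 0.01).

## Worked example

Simulate a quenching titration under the standard acquisition protocol
(averages of three 1%-noise scans on the 310–500 nm grid), apply the 5-point
smoothing, and fit:

```r
library(memfluor)

ts  <- smooth_titration(simulate_titration(f_a = 1, K_SV = 2.5e4, seed = 7), 5)
stern_volmer_fit(ts)
#> Modified Stern-Volmer fit ('compound')
#>   K_SV = 2.540e+04 1/M,  f_a = 0.994,  R = 0.9999 (n = 10, excluded 0)
#>   K_q = K_SV/tau0 = 1.016e+13 1/(M s) (tau0 = 2.5 ns) -> static quenching
scatchard_fit(ts)
#> Scatchard double-log fit ('compound')
#>   K_a = 2.414e+04 1/M,  n = 0.996 sites,  R = 1.0000 (n = 10, excluded 0)
```

The true `K_SV` of 2.5×10⁴ M⁻¹ is recovered within ~2%; `K_q` ≈ 10¹³ M⁻¹s⁻¹
lies three orders of magnitude above the diffusion limit, so the quenching is
static (complex formation), and the Scatchard fit agrees (`n` ≈ 1 site,
`K_a` ≈ `K_SV` as required for 1:1 static quenching).

The same style applies to the other stages:

```r
fit_c50(simulate_fragility(c50 = 0.65, noise_sd = 2, seed = 3))
#> Logistic fragility fit ('treated'): C50 = 0.6481 % NaCl, steepness s = 0.0305

simulate_dunnett_fwer(k = 4, n = 3, alpha = 0.05, reps = 5000, seed = 1)$fwer
#> [1] 0.0506
```

`run_pipeline()` ties the stages together from a config list or YAML file
and returns an `analysis_report` (JSON-serialisable via `write_report()`);
`inst/cli/memfluor` is a thin Rscript wrapper with `simulate`, `quench`,
`probes`, `hemolysis`, `morphology` and `report` subcommands.

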