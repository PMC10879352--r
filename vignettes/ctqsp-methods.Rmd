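---
title: "ctqsp: model, calibration and virtual-trial methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctqsp: model, calibration and virtual-trial methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctqsp)
```

## Scope

`ctqsp` is a quantitative systems pharmacology platform that translates
hiPSC-derived cardiomyocyte (hiPSC-CM) toxicity measurements into predicted
incidences of drug-induced systolic dysfunction (LVEF reduction) for
doxorubicin and trastuzumab, given alone, sequentially or concurrently. It
chains four layers:

1. **Cellular drug exposure** — extracellular concentration histories are
   converted into free intracellular doxorubicin (membrane transport plus
   saturable DNA binding) and internalized trastuzumab (surface ErbB-2
   binding, internalization, endosomal degradation).
2. **Toxicodynamic (TD) core** — myocyte injury and death through a
   three-compartment transit chain; ATP/MMP bioenergetics; chemo-mechanical
   energy transduction producing the average contractile force (ACF).
3. **Systemic translation** — surrogate two-compartment PBPK exposure at the
   heart interstitium, the accessibility scaling
   `E_drug = (SF * ACF)^R_access`, and a minimal stroke-volume/compensation
   model producing LVEF(t).
4. **Virtual trials** — Monte-Carlo patient cohorts, screening and exclusion
   rules, subgroup incidence with bootstrap intervals, dose–response and
   local sensitivity analysis.

## The toxicodynamic model

States: population fractions (`f_nor`, three injured transit compartments,
`f_dead`), normalized `ATP` and `MMP`, and the doxorubicin enhancement state
`E_DOX_TRZ`.

* Injury: `d f_nor/dt = -k_inj * C_in_DOX * f_nor`; injured cells traverse
  three transit compartments of mean time `tau` each before dying. The
  survival fraction is `(f_nor + f_inj)/(f_nor + f_inj + f_dead)`.
* Bioenergetics: MMP production is zero-order and inhibited by free
  intracellular doxorubicin with an Emax model (`Emax_kinMMP = 1`,
  `EC50_kinMMP`); ATP production is stimulated by `(MMP/MMP0)^n` and
  inhibited by internalized trastuzumab (`Emax_kinATP`, `EC50_kinATP`).
* Force: `ACF = ACF_max * ATP/(ATP + ATP50)` with
  `ATP50 = ATP50_ref * (1 + C_in_TRZ * k_TRZ_ATP50 / E_DOX_TRZ)` and
  `dE_DOX_TRZ/dt = -k_e * C_in_DOX * E_DOX_TRZ`: prior or concurrent
  doxorubicin exposure irreversibly amplifies the trastuzumab effect on the
  force apparatus.

Two published estimate sets ship as presets (`td_preset()`): a
doxorubicin-only fit (`k_inj = 0.0023 (h*umol/L)^-1`, `tau = 1.38 h`,
`EC50_kinMMP = 0.36 umol/L`) and the interaction fit (`k_inj = 0.0035`,
`tau = 4.9`, `EC50_kinMMP = 1.87`, `Emax_kinATP = 0.54`,
`EC50_kinATP = 30.11 nmol/L`, `k_TRZ_ATP50 = 0.013 (nmol/L)^-1`,
`k_e = 9.94 (h*umol/L)^-1`), with shared system parameters
(`k_in_ATP = 0.032 h^-1`, `k_in_MMP = 0.96 h^-1`, `CN = 7.21e4 umol/L`,
`n = 0.8`). Where the surrounding literature gives conflicting units for
`EC50_kinATP` and `EC50_kinMMP` (mass-based or nanomolar variants), this
package adopts the tabulated units (nmol/L and umol/L respectively)
throughout.

### Fixed-by-construction quantities

Several constants are tied by baseline constraints rather than fitted, so
drug-free observables stay flat at their normalized baseline of 1:

* `MMP0 = 1`, `Emax_kinMMP = 1` (set by convention);
* `k_out_ATP = k_in_ATP` and `k_out_MMP = k_in_MMP` (baseline steady states
  `ATP(0) = MMP(0) = 1`);
* `ACF_max = 1 + ATP50_ref` (baseline force 1). `ATP50_ref` defaults to 0.5,
  leaving the force model's single free shape constant configurable; the
  package's validation is designed to be insensitive to this choice.

## Cellular exposure defaults and a structural tension

The cellular-transport constants (permeability, cell geometry, partition
ratio, DNA-binding `k_d`, all trastuzumab rate constants) are not estimable
from the calibration data and ship as documented, literature-informed
placeholders (`inst/extdata/default_parameters.yaml`); nothing in the test
suite treats them as ground truth. The defaults were chosen so that:

* free intracellular doxorubicin spans roughly three orders of magnitude
  within a 24 h exposure window (DNA-buffered uptake: total drug accumulates
  quasi-linearly while the free fraction rises hyperbolically), reaching its
  partition ceiling `k_pp * C_ex` near the end of the window. This makes the
  injury parameters (`k_inj`, `tau`), the MMP potency (`EC50_kinMMP`) *and*
  the enhancement rate (`k_e`) simultaneously identifiable from one design:
  the early free-drug integral is small enough that the contractile-force
  collapse in combination arms happens inside the observation grid, whose
  timing pins `k_e`.
* trastuzumab receptor occupancy saturates far below 1 umol/L
  (Kd = `k_off/k_on` = 0.5 nmol/L), so the 1 and 10 umol/L arms produce
  near-identical trajectories, and internalized drug ramps to its steady
  state `Ag_cell * k_int / k_deg` = 40 nmol/L over tens of hours — a range
  that straddles `EC50_kinATP` and keeps the trastuzumab coefficients
  identifiable.

A genuine tension is built into the published parameter set:
`k_e / k_inj ≈ 2800`. Any exposure history that keeps the enhancement state
in its informative range (`k_e * AUC(C_in_DOX) ~ 1`) produces negligible
direct injury, and any exposure producing substantial injury collapses
`E_DOX_TRZ` to zero. In vitro both regimes occur *sequentially within one
time course* thanks to the buffered uptake, which is why the calibration
works. In vivo one scale must be chosen; see "Translation layer" below.

## Data normalization and the synthetic generator

Raw well measurements are normalized in two steps: first to the same well's
pre-treatment (t = 0) value, then to the contemporaneous control ratio
(`normalize_raw()`), which cancels inter-well scale effects and shared
temporal drift. The synthetic generator (`generate_dataset()`) forward
simulates a design preset and applies exactly the noise structure the
normalization targets: per-well lognormal scale effects, a shared sinusoidal
drift (circadian surrogate, default ±5% over 24 h), and lognormal
measurement error per observation (default CV 10%). Baseline and
control-arm records are treated as averaged, effectively noise-free
measurements (multiple fields of view per well, pooled control wells), so a
normalized observation carries the configured measurement CV — not the
inflated variance of a ratio of four noisy quantities. The generator shares
its simulation engine with the calibration objective, so noise-free data are
refit exactly.

Design presets mirror the two calibration experiments: `fig1a` (doxorubicin
0–20 umol/L by 6–72 h exposure windows; endpoints ACF, survival fraction,
ATP, MMP; observations at 0–72 h) and `fig1b` (doxorubicin 5 umol/L for
24 h and trastuzumab 1 or 10 umol/L alone, sequential or concurrent;
endpoints ACF, survival fraction, ATP). Replicates default to 3. What the
generator does *not* emulate: batch-to-batch differentiation variability,
assay-specific detection floors, plate-edge effects, or any recovery of
injured cells — so passing recovery tests demonstrates estimator
correctness under the stated error model, not robustness to every feature
of real assay data.

## Parameter estimation

The estimation scheme is two-stage pooled weighted least squares (the
population-level stochastic-approximation machinery used in the original
calibration adds nothing for pooled single-cell-line data):

* **Stage 1** (`fit_stage1_dox()`): system-dependent parameters
  (`k_in_ATP`, `k_in_MMP`, `CN`, `n`) plus the doxorubicin individual
  parameters (`k_inj`, `tau`, `EC50_kinMMP`) from the doxorubicin panel.
* **Stage 2** (`fit_stage2_interaction()`): all of the above plus the
  trastuzumab and interaction coefficients (`Emax_kinATP`, `EC50_kinATP`,
  `k_TRZ_ATP50`, `k_e`), simultaneously, from the interaction panel;
  stage-1 estimates may seed the shared parameters.

Numerical choices, each of which matters:

* Residuals are `log(pred) - log(obs)` — exactly the generator's
  multiplicative error model, and homoscedastic across endpoints, so the
  default per-endpoint weights are 1 (a pooled-SD weighting remains
  available via the `weights` argument).
* A limit of quantification (`loq`, default 1e-3 of baseline) floors both
  observations and predictions before taking logs. Fully collapsed
  contractile-force signals sit below any realistic assay resolution;
  without the floor they produce unbounded, purely numerical residuals.
* Parameters are optimized on the log10 scale with bounded
  Levenberg–Marquardt (`minpack.lm::nls.lm`), multi-start (default 5
  starts: the initial values plus log-uniform draws within a 3-fold box,
  seeded). Default bounds are a 10-fold box around the initial values.
  The box is deliberately a plausible-range constraint: the injury/transit
  sub-model admits a distant competing mode — near-instant injury feeding a
  very slow transit chain — that is almost indistinguishable from the
  gradual-injury truth on a 72 h window, and an unbounded search will
  sometimes land there. Both stages are refinements of published or
  stage-1 values, which is what the box encodes.
* Relative standard errors come from the Gauss–Newton curvature at the
  optimum through an SVD pseudo-inverse, so flat (non-identifiable)
  directions yield huge-but-finite RSEs; parameters above the
  `identifiability_rse` threshold (default 50%) are flagged rather than
  silently reported. Single-concentration designs flag `EC50_kinMMP`;
  designs without sequential/concurrent arms flag `k_e`.
* Known estimator property: at measurement CV 0.10 the sampling
  distributions of the effect-scale parameters are noticeably skewed; in the
  package's own 20-replicate simulation studies the medians of `k_e` and
  `k_inj` sit roughly 10–15% below the generating values (the bias shrinks
  with the noise CV, i.e. the estimator is consistent). `tau` and the
  stage-1 parameters recover essentially unbiased.

## Translation layer

* **Exposure.** Each drug gets a linear two-compartment disposition
  surrogate (closed-form infusion responses, superposed), scaled by a
  heart-interstitial access factor. Defaults approximate published human
  pharmacokinetics (doxorubicin CL 55 L/h, terminal half-life ~1 day;
  trastuzumab CL 0.012 L/h, half-life ~2 weeks).
* **Effect scaling.** `E_drug = (SF * ACF)^R_access` with `R_access = 1` in
  vitro and 0.12 in vivo (reduced drug accessibility of cardiomyocytes in
  3D tissue).
* **Cardiac response.** Stroke volume is `SV0 * E_drug(t) * Comp(t)`; the
  compensation state relaxes first-order (time constant `tau_comp`, default
  96 h) toward `min(1 + gain*(1/E_drug - 1), ceiling)` (defaults: gain 1,
  ceiling 1.2). Comorbid patients (MAP >= 115 mmHg or LVEDV >= 146 mL) have
  `gain` and `ceiling - 1` halved. LVEF(t) = SV/LVEDV * 100.
* **Dysfunction.** Default classifier: a drop of more than 10 LVEF points
  from baseline or absolute LVEF below 50% — the reading consistent with
  the screening criterion "baseline LVEF >= 50%". The literal-text
  alternative (relative 10% drop or below 50% of baseline) is selectable;
  nothing asserts which reading the original authors intended.

**Calibration of the surrogate.** The compensation constants and the
doxorubicin access factor cannot be identified from cellular data; they were
fixed once so that the default virtual population reproduces the published
predicted incidence bands for the two clinically validated regimens
(trastuzumab monotherapy 0.31–2.7%; sequential doxorubicin→trastuzumab
0.15–10%) with mid-band values, and the published cohort composition
(~37% comorbid; ~0.4% screened out for baseline LVEF < 50%). With the
default doxorubicin access factor (0.006), the standard 240 mg/m² course
leaves `E_DOX_TRZ ≈ 0.33` — the enhancement state stays in its sensitive
range, which is what makes the sequential and concurrent regimens riskier
than monotherapy. The flip side of this choice (see the tension above) is
that *direct* doxorubicin injury in vivo is negligible: the
doxorubicin-alone dose–response is essentially flat at zero incidence, and
the injury rate constant `k_inj` carries almost no sensitivity in the
in-vivo analysis. Under the irreversible enhancement dynamics the model
also predicts sequential treatment to be at least as risky as concurrent
treatment at the 64-week horizon (the sequential arm has a sharper onset
and a longer trastuzumab tail); a concurrent-worse ordering would require
an active direct doxorubicin pathway in vivo, which the adopted parameter
units exclude. Both consequences are inherent to the published parameter
scales, not tunable defects, and the corresponding acceptance checks are
left to fail honestly.

## Virtual trials

`sample_patients()` draws every positive parameter lognormally around its
median: TD individual parameters with the calibration's reported relative
standard errors as CVs (8.5–25%), pharmacokinetic scalars at 30%, and
physiology (weight, BSA, MAP, LVEDV, baseline ejection fraction) with CVs
set to reproduce the published cohort composition. Each patient owns a
L'Ecuyer-CMRG substream derived from the master seed, so cohorts are
bit-reproducible and enlarging a cohort never changes existing patients.
Screening keeps patients with baseline LVEF >= 50%; regimens that
administer trastuzumab after time zero additionally exclude patients who
became dysfunctional before the first trastuzumab dose.

Regimen presets follow the validation protocols: doxorubicin 60 mg/m² every
3 weeks (cumulative 60–960 mg/m², incidence read 52 weeks after the first
dose); trastuzumab 2 mg/kg weekly for 52 weeks with an additional 2 mg/kg
in the first week (4 mg/kg loading); sequential and concurrent combinations
thereof, read at week 64. Incidence is reported overall and by
cardiovascular subgroup with seeded bootstrap percentile intervals
(default 200 resamples).

`sensitivity_analysis()` perturbs one TD parameter at a time (folds in
[1/3, 3], every patient's sampled value scaled) on the same cohort and seed
and reports the normalized sensitivity
`(p/Incidence) * (dIncidence/dp)` against the unperturbed trial.

## Numerical engines and problem sizes

Two integration paths exist deliberately:

* an adaptive stiff-capable path (`deSolve::lsoda`, default relative
  tolerance 1e-8, absolute 1e-12) with hard restarts at every exposure
  discontinuity — the reference used by `simulate_td()` and the analytic
  test oracles; and
* a compiled fixed-step engine (default step 0.05 h in vitro, 0.5 h for
  trials) using exponential exact-for-frozen-input updates for every linear
  sub-system and an RK4 substep for the nonlinear doxorubicin uptake —
  unconditionally stable in the stiff binding limits, globally
  second-order, and the workhorse behind calibration and the trial layer.
  PBPK states are stepped exactly in modal coordinates, including exact
  per-step exposure integrals.

The test suite pins the two paths against each other and against
independent fixed-step RK4 references, and checks fraction conservation to
1e-8 and the analytic closed forms to 1e-5.

Default study sizes (chosen as routine desk-scale workloads): recovery
studies use 20 replicate generate/refit cycles at 3 optimization starts;
trials use 2,000–6,000 generated patients (6,000 guarantees at least 2,000
per cardiovascular subgroup at the default comorbidity fraction);
sensitivity uses ~1,200 patients per perturbed trial.

## Known limitations

* No recovery/proliferation term: injury and the enhancement state are
  irreversible, which drives the sequential-vs-concurrent ordering noted
  above.
* The cardiac response layer is a deliberate minimal surrogate with one
  documented contract (`E_drug` multiplies stroke volume); incidence
  magnitudes are calibrated, so only bounded and ordinal statements about
  incidence are meaningful.
* Cellular transport constants are placeholders; absolute intracellular
  concentrations should not be interpreted quantitatively.
* The estimator's small but systematic downward skew of `k_e` at 10%
  measurement noise (above) is a property of bounded nonlinear least
  squares on this design, not of the model.
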