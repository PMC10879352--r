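# ctqsp — translational modelling of antineoplastic drug-induced systolic dysfunction

`ctqsp` is a quantitative systems pharmacology (QSP) toolkit for predicting
the clinical incidence of drug-induced left-ventricular ejection fraction
(LVEF) reduction from **in-vitro hiPSC-derived cardiomyocyte (hiPSC-CM)
experiments**, built around doxorubicin and trastuzumab given alone,
sequentially, or concurrently. It is aimed at pharmacometricians and
cardio-oncology modellers who want to go from plate-level contractility,
viability, ATP and mitochondrial-membrane-potential (MMP) time courses to
virtual-patient trial predictions in one reproducible pipeline.

## The model in brief

Cellular exposure converts extracellular concentrations into the drivers of
toxicity — free intracellular doxorubicin `C_DOX` (membrane transport with
saturable DNA binding, `C_free + CN·C_free/(k_d + C_free) = C_total`) and
internalized trastuzumab `C_TRZ` (ErbB-2 binding/internalization). The
toxicodynamic core is:

```
df_nor/dt   = −k_inj·C_DOX·f_nor               (injury)
f_inj chain = three transit compartments, mean time τ each → f_dead
dMMP/dt     = k_in_MMP·(1 − C_DOX/(C_DOX+EC50_kinMMP)) − k_out_MMP·MMP
dATP/dt     = k_in_ATP·(MMP/MMP0)^n·(1 − Emax_kinATP·C_TRZ/(C_TRZ+EC50_kinATP)) − k_out_ATP·ATP
ACF         = ACF_max·ATP/(ATP + ATP50),  ATP50 = ATP50_ref·(1 + C_TRZ·k_TRZ_ATP50/E)
dE/dt       = −k_e·C_DOX·E                     (doxorubicin→trastuzumab synergy)
SF          = (f_nor + f_inj)/(f_nor + f_inj + f_dead)
```

For the in-vivo translation, `E_drug = (SF·ACF)^R_access` (R_access = 0.12
in tissue) multiplies stroke volume in a compensated cardiac response model,
yielding LVEF(t) per virtual patient; systolic dysfunction is a >10-point
LVEF drop from baseline or absolute LVEF < 50%. Monte-Carlo cohorts with
published inter-individual dispersions produce incidence by cardiovascular
subgroup, dose–response curves, and local sensitivities
`(p/Incidence)·(ΔIncidence/Δp)`.

See the methods vignette (`vignettes/ctqsp-methods.Rmd`) for assumptions,
parameter tables, numerical choices and known limitations.

## Worked example

Generate a synthetic doxorubicin exposure–duration panel at the published
parameters, re-estimate the model from it, and run a trastuzumab
monotherapy virtual trial:

```r
library(ctqsp)

ds <- generate_dataset("fig1a", td_params = td_preset("dox_only"),
                       noise = noise_model(cv = 0.10), seed = 1)
ds
#> <invitro_dataset> 26 arms, 2184 normalized records, 4 endpoints

fit <- fit_stage1_dox(ds, n_starts = 3, seed = 1)
fit
#> <td_fit> 7 parameters, 1872 observations; SSR = 19.032
#>              estimate rse_pct
#> k_in_ATP    3.112e-02     1.9
#> k_in_MMP    9.360e-01     4.0
#> CN          7.192e+04     0.7
#> n           8.295e-01     2.5
#> k_inj       2.297e-03     1.2
#> tau         1.415e+00     9.9
#> EC50_kinMMP 3.580e-01     1.0

run_trial(trial_spec("TRZ", n = 2000, seed = 1))
#> <trial_result> TRZ - 1989 patients analysed ( 11 screened out, 0 excluded pre-trastuzumab )
#>   subgroup    n n_dysfunction incidence_pct ci_lo ci_hi
#> 1  overall 1989             6         0.302 0.101 0.553
#> 2   normal 1262             3         0.238 0.000 0.634
#> 3 comorbid  727             3         0.413 0.000 0.963
```

The refit recovers the generating values (for example `k_inj` 0.0023
(h·µmol/L)⁻¹ and `EC50_kinMMP` 0.36 µmol/L) within a few percent, with
relative standard errors from the objective curvature. The trial screens
out patients with baseline LVEF < 50%, simulates every remaining patient
through the exposure→toxicodynamics→cardiac-response chain, and reports the
week-64 dysfunction incidence per cardiovascular subgroup (comorbid =
hypertension or dilated cardiomyopathy) with bootstrap 95% intervals —
here ~0.3% overall, higher in the comorbid subgroup, consistent with the
rarity of trastuzumab-monotherapy cardiotoxicity.

A thin command-line wrapper (`inst/scripts/ctqsp`) exposes the same
pipeline (`generate-synthetic`, `fit`, `run-trial`, `dose-response`,
`sensitivity`, ...), writing a run manifest next to every output.

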