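# cellobind

Quantitative analysis of carbohydrate-binding module (CBM) and processive
cellulase binding to crystalline cellulose allomorphs — native cellulose I
versus ammonia-pretreated cellulose III.

Processive exocellulases such as *T. reesei* Cel7A are anchored to cellulose
by a CBM whose planar aromatic motif stacks on the fibre's hydrophobic face.
How strongly and in which orientation that motif binds controls the enzyme's
initial *motility commitment* and its subsequent ~1-nm processive steps.
`cellobind` provides the full analysis tool-chain used to quantify these
interactions across six assay families, plus seeded synthetic-data
generators for every input type, so the whole pipeline is testable without
instrument data. It is aimed at single-molecule biophysicists and
carbohydrate-enzymology labs analysing tweezer, pull-down, FRAP, QCM-D and
XRD data.

## What it computes

| Stage | Model / statistic |
|---|---|
| `isotherm` | Langmuir one-site `B = n_max F/(K_d+F)`, two-site sum, Langmuir–Freundlich `B = n_max F^m/(K_d^m+F^m)`; partition coefficient (initial slope); truncation sensitivity; Scatchard curvature |
| `motility` | penalized change-point step detection; dwell-time exponential MLE with censoring and dead-time corrections; sign-resolved Gaussian step-size mixtures; velocity; 10-s commitment rule |
| `rupture` | 2.5-pN force binning; weighted Bell slip-bond fit `tau(F) = tau0 exp(-F x'/kBT)`; exponential mixture-order selection by parametric-bootstrap LRT; one-way ANOVA |
| `kinetics` | reaction-dominated FRAP `I(t) = b + F_M (1-e^{-k_off t})`; QCM-D Langmuir kinetics with Sauerbrey conversion `Δm = -C Δf/n` |
| `buffon` | needle-on-parallel-lines orientation model, `P(cross) = 2L/(πd)`, Monte-Carlo for any `L/d` |
| `xrd` | peak matching at allomorph Bragg angles; Segal crystallinity `(I_max-I_am)/I_max`; Scherrer size `Kλ/(β cos θ)` |

## Worked example

```r
library(cellobind)

# synthetic pull-down dataset at the GFP-CBM1 / cellulose I reference
# parameters, then refit
d <- gen_isotherm(isotherm_gen_config(
  model_id = "one_site", params = c(n_max = 4.34, K_d = 8.69),
  noise_sd = 0.1, seed = 1))
fit_isotherm(d, "one_site")
#> Isotherm fit [one_site], n=20, converged=TRUE, RMSE=0.08695 umol/g
#>       estimate     se
#> n_max   4.3870 0.0543
#> K_d     8.8272 0.4340

# a one-minute motility staircase at 1 kHz, and its step/dwell analysis
tr <- gen_motility_trace(trace_gen_config(
  dwell_mean = 0.75, back_step_prob = 0.35, noise_sd = 0.3, seed = 2))
detect_steps(tr)
#> Step/dwell series: 73 steps, mean |step| 1.21 nm, mean dwell 0.81 s

# full cellulose I vs III synthetic comparison
report <- run_pipeline(default_run_config(master_seed = 7))
report
#> Cellulose I vs cellulose III comparison report
#>   stages: isotherm, motility, rupture, kinetics, buffon, xrd
#>   master seed: 7
#>   velocity_reduction_pct       53.4
#>   commitment_reduction_pct     75
#>   kd_fold_change               1.145
#>   partition_ratio_I_over_III   1.489
#>   mean_lifetime_diff_s         0.1932
#>   frap_koff_fold               1.91
#>   qcmd_koff_fold               2.457
```

The fitted `n_max`/`K_d` recover the generating values within their standard
errors; the report's deltas are III-relative-to-I changes computed from the
synthetic stages (velocity reduction in percent, `K_d` and `k_off` fold
changes as ratios, mean bond-lifetime difference in seconds). A YAML config
can replace the defaults (`run_pipeline(read_run_config("config.yaml"))`),
and `inst/scripts/run_pipeline.R` wraps this for shell use.

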