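# wbam

Frontal whole-body angular momentum (WBAM) gait analysis and Bayesian
pre/post rehabilitation-effect modelling, in one tested R package.

## What it is for

Walking after a stroke is asymmetric, and the body's frontal-plane
angular momentum — the side-to-side rocking momentum about the
anterior–posterior axis through the centre of mass — reflects that
directly. Its **range over one gait cycle** is a compact dynamic-balance
outcome for rehabilitation studies. This package serves analysts of such
studies twice over:

1. **Kinematics.** From segment-level motion capture (120 Hz positions,
   optional 1200 Hz vertical ground-reaction force) it computes

   *L(t) = Σᵢ {(rᵢ − r_CM) × mᵢ(vᵢ − v_CM) + Iᵢωᵢ}*,

   the 12-segment frontal WBAM about the body CoM (positive toward the
   non-paretic side), after zero-phase 4th-order Butterworth smoothing
   (6 Hz kinematics / 80 Hz force), detects paretic foot contacts,
   time-normalizes each cycle to 101 points, scales by body mass ×
   height × walking speed, and returns the per-cycle range
   *L_r = max L(t) − min L(t)*.

2. **Inference.** On a trial-level dataset of pre/post range pairs it
   fits four Bayesian models of the multiplicative training effect
   `post ~ Normal((β_CT + g·β_AF)·pre, σ)` — treadmill effect β_CT for
   everyone, additional auditory-feedback effect β_AF for the AF group —
   differing in whether each effect varies by patient around population
   hyperparameters. Models are ranked by WAIC computed from the
   **marginalized** (new-patient) predictive density, convergence is
   checked with split-R̂ (< 1.10), and effects are reported as posterior
   means, 95% percentile intervals, percent reductions, exact
   mixture-quantile predictive bands, and a standardized effect size.

A seeded synthetic-cohort and synthetic-gait generator (with closed-form
WBAM attached) makes the whole pipeline testable without clinical data.

## Worked example

```r
library(wbam)

ds    <- generate_cohort(cohort_config(seed = 42))  # 8 AF + 8 CT patients, 5 paired trials
pairs <- pair_trials(ds)
cmp   <- compare_models(pairs, mcmc = mcmc_config(seed = 42))
cmp$table
#>   model      waic     lppd   p_waic   d_waic rank
#> 1     1 -612.0113 309.1772 3.171582 0.000000    1
#> 2     3 -609.7347 308.6139 3.746545 2.276568    2
#> 3     2 -609.5474 309.1136 4.339849 2.463823    3
#> 4     4 -608.1020 308.5462 4.495214 3.909293    4

fit1 <- cmp$fits[["1"]]
effect_summary(fit1)
#>     effect    mean   lower   upper
#> 1  beta_ct  1.0456  1.0163  1.0756
#> 2  beta_af -0.2097 -0.2579 -0.1592
#> 3 combined  0.8359  0.7979  0.8744

pr <- percent_reduction(effect_draws(fit1)$af)
sprintf("AF reduction: mean %.1f%%, 95%% interval %.1f-%.1f%%", pr$mean, pr$lower, pr$upper)
#> "AF reduction: mean 21.0%, 95% interval 15.9-25.8%"
```

Reading: the cohort was generated with true effects β_CT = 1.046 (the
treadmill alone leaves the range unchanged) and β_AF = −0.209 (feedback
shrinks it by ~21%), and no patient-level effect variation. The fit
recovers both truths inside tight intervals, and the non-hierarchical
model 1 correctly wins the marginalized-WAIC ranking — the hierarchical
models pay a new-patient predictive penalty for effect variation the
data do not contain.

The kinematics half, end to end on synthetic gait:

```r
trial <- generate_synthetic_gait(gait_config(seed = 3))
res   <- trial_wbam_ranges(trial, smooth = FALSE)
res$ranges           # dimensionless per-cycle WBAM range
#> 0.01059926 0.01059926 0.01059926 0.01059926
```

A full run (simulate → fit 1–4 → rank → tables → predictive bands →
manifest) is one call, or one shell command via the thin CLI:

```r
run_pipeline(pipeline_config(seed = 1), "out/")   # writes ranges.csv,
# table2.csv, table3.csv, bands.csv, manifest.json
```

```sh
Rscript inst/cli/wbam.R run --config analysis.yaml --out out/
```

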