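---
title: "Methods: frontal WBAM gait analysis and Bayesian pre/post effect models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frontal WBAM gait analysis and Bayesian pre/post effect models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbam)
```

## The problem

Hemiparetic gait after stroke is asymmetric, and that asymmetry shows up
directly in the body's frontal-plane angular momentum: the side-to-side
"rocking" momentum that the central nervous system normally keeps tightly
regulated during walking.  The range of the frontal whole-body angular
momentum (WBAM) over one gait cycle is therefore a compact dynamic-balance
outcome for walking rehabilitation studies.  This package implements the
two halves of such an analysis:

1. **Kinematics** — computing the frontal WBAM time series and its
   per-cycle range from segment-level motion-capture data;
2. **Inference** — fitting and comparing four Bayesian models of how a
   two-week rehabilitation program (treadmill training, with or without an
   auditory-feedback prosthesis) changes that range from pre to post,
   including prediction for a new, unseen patient.

Because trial-level clinical recordings of this kind are generally not
public, the package also ships a seeded synthetic-cohort and
synthetic-gait generator so that every stage of the pipeline is testable
against known ground truth.

## Whole-body angular momentum

The body is modelled as 12 rigid segments (trunk/thorax, pelvis, and
paretic/non-paretic upper arms, forearms, thighs, shanks and feet; head
and hands excluded).  The WBAM about the body centre of mass (CoM) is

$$
L(t) \;=\; \sum_{i=1}^{12}
\Big\{ \big(r_i(t) - r_{CM}(t)\big) \times m_i \big(v_i(t) - v_{CM}(t)\big)
      \;+\; I_i\,\omega_i(t) \Big\},
$$

the sum of a *transfer* term (each segment's CoM motion about the body
CoM) and a *local* term (each segment's spin about its own CoM).  The lab
frame is right-handed with X anterior, Y to the subject's left and Z up;
the frontal-plane WBAM is the X component.  The sign is mirrored for
right-paretic subjects so that positive values always mean momentum
toward the non-paretic side.  The per-cycle outcome is the range

$$
L_r \;=\; \max_t L(t) - \min_t L(t), \qquad t \in [0\%, 100\%]
\text{ of the gait cycle},
$$

computed on the series normalized by body mass (kg) × height (m) ×
walking speed (m/s), which makes ranges comparable across subjects.

Implementation notes and conventions:

* **Filtering.** Marker/segment coordinates are smoothed with a
  bidirectional (zero-phase) fourth-order Butterworth low-pass filter,
  cut-off 6 Hz; vertical ground-reaction force (GRF) with the same design
  at 80 Hz.  "Bidirectional fourth-order" is read as a 4th-order design
  applied forward and backward, so the amplitude gain at the cut-off is
  $(1/\sqrt 2)^2 = 0.5$ and the effective magnitude response is
  8th-order.  The passes start from the filter's step-response steady
  state after odd-reflection padding, so constants pass through exactly
  (unit DC gain) and edge transients are suppressed.
* **Gait events.** Paretic foot contact is the rising edge of the
  vertical GRF through 20 N (a common force-plate default), mapped from
  the force-plate rate (1200 Hz) to the kinematic rate (120 Hz).  Without
  GRF, local minima of the paretic-foot CoM height are used, merged so
  that detected cycles are at least 0.5 s apart.
* **Time normalization.** Each cycle (contact to next contact) is
  linearly interpolated onto a 101-point grid (0, 1, ..., 100% of the
  cycle), endpoints preserved exactly.  For signals band-limited by the
  6 Hz filter, the interpolation error of this grid is well inside the
  1% budget that the end-to-end tests enforce.
* **Inertia.** Segment masses and frontal-axis moments of inertia come
  from a configurable anthropometric table
  (`inst/extdata/bsip_dumas2007.csv`, approximate adult-male values after
  Dumas et al. 2007; any table with the same columns may be supplied).
  The local term uses a scalar (isotropic) or diagonal lab-frame inertia:
  the package's CSV interface carries segment CoM positions and angular
  velocities but no orientation time series, so a per-sample rotation of
  the full inertia tensor is not computable from the declared inputs.
  For frontal-plane walking analysis the transfer term dominates and the
  local term is small; the simplification is stated rather than hidden.
* **Angular velocity.** When only positions are supplied, CoM velocities
  are derived by central finite differences at the sampling rate
  (one-sided at the series ends); angular velocities default to zero.
  Marker input via the proximal/distal endpoint convention
  (`segments_from_markers()`) likewise carries no spin information.

Two invariances pin down the implementation and are asserted in the test
suite: adding any constant velocity to all segments and to the body CoM
leaves WBAM unchanged to 1e-10 relative (Galilean invariance, exact
because the body CoM is the mass-weighted mean of the segment states),
and WBAM is additive over disjoint segment sets about a common CoM.

## The four pre/post effect models

Let $y^{pre}_{ij}$ and $y^{post}_{ij}$ be the normalized WBAM range of
trial $i$ of patient $j$ before and after the two-week program.  All four
models share the multiplicative observation law

$$
y^{post}_{ij} \sim \mathrm{Normal}\!\big(\beta\, y^{pre}_{ij},\ \sigma\big),
\qquad
\beta = \beta_{CT} + g_j\,\beta_{AF},
$$

where $g_j = 1$ for auditory-feedback (AF) patients and 0 for controls
(CT): $\beta_{CT}$ is the treadmill-training effect shared by both arms
and $\beta_{AF}$ the additional feedback effect.  A value $\beta < 1$
means the range shrank.  The models differ in whether the effects vary by
patient:

| model | patient-level effects |
|-------|----------------------|
| 1 | none |
| 2 | $\beta_{CT,j} \sim \mathrm{Normal}(\mu_{CT}, \sigma_{CT})$ |
| 3 | $\beta_{AF,j} \sim \mathrm{Normal}(\mu_{AF}, \sigma_{AF})$ |
| 4 | both |

One deliberate reading: the observation law is regressed on the **pre**
value.  (A literal transcription of the non-hierarchical model's printed
form would regress the post value on itself; the pre/post linear
relation that motivates all four models makes clear this is a typo, and
models 2–4 are printed with the pre value.)

**Pairing.** The models index pre and post by the same trial number, so
trials must be paired within patient.  The default rule pairs the i-th
pre trial with the i-th post trial in ascending trial order, truncating
to the smaller count with a warning; a `pre_mean` mode instead regresses
every post trial on the patient's mean pre value.  Neither rule is
canonical — the pairing convention is a genuine free choice and both are
logged.

**Priors.** All effect-type parameters get non-informative
$\mathrm{Uniform}(-5, 5)$ priors; all scale-type parameters get
$\mathrm{Uniform}(0,\ 10 \times \mathrm{sd}(y^{post}))$ — scale-aware so
the bound adapts to the data's units without ever being informative in
practice.  Both bounds are configurable in `model_spec()`.

**Sampling.** The posterior is sampled with JAGS (Gibbs/slice updates)
via `rjags`; the models are small and conjugate-friendly, and the
sampler contract — draws targeting the joint posterior under the stated
priors — is what the package tests, not the toolchain.  Hierarchies use
the *non-centered* parameterization
($\beta_{CT,j} = \mu_{CT} + \sigma_{CT}\,\eta_j$, $\eta_j \sim
\mathrm{Normal}(0,1)$): when the true effect variation is near zero the
centered form has a funnel geometry that a Gibbs sampler explores
poorly, and in development runs it produced split-$\hat R$ values at the
1.10 boundary on model 4; the non-centered form stays below 1.05 on the
same data.  Chains are seeded deterministically (`seed + chain`) with
over-dispersed initial values.  Defaults: 4 chains, 2000 iterations with
1000 warm-up (adaptation counts toward warm-up).

**Convergence.** `compute_rhat()` implements the split Gelman–Rubin
potential scale reduction factor: every chain is halved, and
$\hat R = \sqrt{\big(\tfrac{n-1}{n} W + \tfrac{1}{n} B\big) / W}$ over
the resulting sequences.  Zero total variance returns 1 by convention.
Any monitored parameter at or above 1.10 flags the fit; flagged fits are
returned but `effect_summary()` refuses them unless forced, and the
pipeline marks them in its manifest.

## Model comparison for a new patient

The question the comparison answers is predictive: which model best
anticipates the rehabilitation effect in a patient *not in the data*?
For the hierarchical models this requires integrating out the
patient-level effects, which is available in closed form because
everything is normal and linear:

$$
y^{post} \sim \mathrm{Normal}\!\Big( (m_{CT} + g\,m_{AF})\,y^{pre},\
\sqrt{(s_{CT}^2 + g\,s_{AF}^2)\,(y^{pre})^2 + \sigma^2} \Big),
$$

with $(m, s)$ the population mean and scale of each effect ($s = 0$ for
non-hierarchical effects).  `marginal_loglik()` implements this and is
verified against brute-force numeric quadrature of the conditional
likelihood (to 1e-6 on random parameter sets) and against Monte-Carlo
averaging over sampled patient effects.

WAIC is computed from the draws-by-observations matrix of these
marginalized log densities:

$$
\mathrm{lppd} = \sum_n \log \tfrac1S \sum_s e^{\ell_{sn}}, \quad
p_{\mathrm{WAIC}} = \sum_n \mathrm{Var}_s(\ell_{sn}), \quad
\mathrm{WAIC} = -2\,(\mathrm{lppd} - p_{\mathrm{WAIC}}),
$$

with a stable log-sum-exp.  Only **differences** (dWAIC) and **ranks**
are meaningful across software: absolute WAIC values depend on scale
conventions that vary between implementations, so the package validates
ranking behaviour, not absolute values.  A conditional-likelihood WAIC
(no marginalization) is available as a non-default option for
within-sample comparisons.

## Effect summaries

* `effect_summary()` — empirical posterior means and equal-tailed 95%
  percentile intervals (2.5/97.5) of $\beta_{CT}$, $\beta_{AF}$ and the
  drawwise combination $\beta_{CT} + \beta_{AF}$ (hyper-means for
  hierarchical models).
* `percent_reduction()` — the feedback effect as a percentage,
  $-100\,\beta_{AF}$ applied drawwise.
* `predictive_interval_curve()` — for each pre value on a grid, the
  per-draw marginal predictive normals are pooled into their exact
  mixture and the 50%/95% central bands are found by root-finding on the
  mixture CDF (tolerance 1e-10), so the bands carry no extra simulation
  noise; the mean line passes through the origin.  For hierarchical
  models the band half-width grows with the pre value, since the
  marginal s.d. is $\sqrt{s^2 (y^{pre})^2 + \sigma^2}$.
* `cohen_d()` — a standardized effect size between the CT-group effect
  draws and the AF-group effect draws: drawwise
  $|d_s| = |ct_s - af_s| / \sqrt{(s_{ct}^2 + s_{af}^2)/2}$ with $s$ the
  empirical standard deviation of each draw set.  The scale terms are
  standard deviations, not variances: reported group-effect "variance"
  values of order 0.16–0.19 reproduce $d \approx 1.17$ only when used as
  standard deviations, so that is the documented convention.  The
  summary also reports the standardized difference of the means, which
  is the quantity a deterministic check can pin down exactly.

## The synthetic generators

**Cohorts** (`generate_cohort()`): per patient a log-normal pre-range
"bias" $b_j$ (default meanlog $\log 0.03$, sdlog 0.5, spanning roughly
0.01–0.1 dimensionless units — the decade typical of
mass·height·speed-normalized WBAM ranges, chosen once as a realism
assumption since trial-level magnitudes are not published numerically);
per trial a pre value $b_j(1 + 0.05 z)$ (5% multiplicative trial noise,
set 0 to match the model equations exactly) and a post value from the
hierarchical law itself.  Defaults are the study layout: 8 + 8 patients,
5 paired trials, population truths $\beta_{CT} = 1.046$,
$\beta_{AF} = -0.209$, no patient-level variation, observation noise
$\sigma = 0.005$.  Posts that would come out negative (possible only in
the extreme noise tail, probability $<10^{-3}$ per trial at the
defaults) are redrawn so the non-negativity invariant of ranges holds;
the induced truncation bias is negligible at these settings.  The truths
are attached as a ledger and written as a sidecar JSON by
`write_cohort()`.  Stratified `block_randomize()` (seeded, balanced
within strata to ±1) emulates the trial's randomization when strata are
supplied.

**Gait** (`generate_synthetic_gait()`): each segment's CoM oscillates
sinusoidally in the frontal plane with exact analytic velocities
attached, left/right limb pairs share amplitudes and circulate
oppositely (lateral antiphase, vertical in phase) so a symmetric gait
has cancelling side momenta, and the paretic side's lateral amplitudes
are scaled by an asymmetry factor — more asymmetry, wider WBAM range.  A
square-pulse GRF marks cycle starts.  The generated trial carries a
closed-form `analytic_wbam(t)` evaluated from the exact positions and
velocities, which the pipeline must reproduce to 1e-8 pointwise.

What the generators deliberately do **not** emulate: marker soft-tissue
artefact and noise, segment spin (beyond an optional constant trunk
spin), double-support GRF shapes, patient dropout, and any covariate
structure (paresis scores etc. appear only as optional strata).  Passing
tests therefore certify the computational pipeline — filtering, event
detection, momentum arithmetic, sampling, marginalization, ranking — not
the clinical realism of any particular dataset.

## Numerical choices and degenerate inputs

* Interval estimates use R's default empirical quantiles (type 7);
  WAIC's variance penalty uses the unbiased sample variance.
* `rank_models()` breaks WAIC ties by ascending model id; the best
  model's dWAIC is exactly 0; ranking is invariant to permutation and to
  adding a constant to all WAICs.
* Degenerate inputs fail loudly with typed conditions: series too short
  to filter or to take a range, cut-off at/above Nyquist, missing
  segments, non-positive normalization constants, zero-variance draws in
  Cohen's d, patients missing a phase, CT-only data for models with
  $\beta_{AF}$ (an identifiability error), single chains or single draws
  for $\hat R$/WAIC.
* All generators are pure functions of (config, seed); the pipeline
  manifest records seeds and output digests, and an identical
  configuration reproduces bit-identical outputs.

## Problem sizes used by the checks

The package's own acceptance checks run at the study's scale: 20 seeded
cohorts of 8 + 8 patients × 5 paired trials for parameter recovery
(95% intervals must cover both truths in at least 17/20 runs), 20 more
for model selection (model 1 must win the marginalized-WAIC ranking in
at least 80% of replicates when the data contain no patient-level
variation), 100 random parameter sets for the quadrature check of the
marginal likelihood, and default MCMC settings throughout with every
split-$\hat R$ required below 1.10.

## Known limitations

* The local (spin) term uses scalar/diagonal inertia; studies needing
  full tensor transport must supply orientation-resolved inputs the CSV
  interface does not define.
* Marker endpoint input reconstructs CoM translation only.
* The observation law is homoscedastic in absolute units; if trial noise
  scales with the pre value, the hierarchical scales partially absorb
  it.
* Absolute WAIC values are implementation-specific; compare only
  differences and ranks across software.
* The pairing of pre to post trials is a convention, not data; switching
  pairing modes perturbs fits at the level of the trial noise.
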