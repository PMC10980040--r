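---
title: "Hierarchical multivariate quantification of PET time-activity curves"
author: "hbpet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical multivariate quantification of PET time-activity curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbpet)
```

## The problem

Dynamic PET quantification estimates, per subject and brain region, the
kinetic parameters of a compartment model describing the exchange of a
radioligand between arterial plasma and tissue. For a serotonin-1A
antagonist tracer quantified with the two-tissue compartment model (2TCM),
the parameters are the delivery rate $K_1$ (mL·cm$^{-3}$·min$^{-1}$), the
non-displaceable distribution volume $V_{ND} = K_1/k_2$, the specific
binding ratio $BP_{ND} = k_3/k_4$, the dissociation rate $k_4$
(min$^{-1}$) and the fractional blood volume $v_B$. Binding potential can
be expressed relative to non-displaceable uptake ($BP_{ND}$), to total
plasma parent concentration ($BP_P = V_{ND}\,BP_{ND}$) or to the free
plasma concentration ($BP_F = BP_P/f_P$, with $f_P$ the plasma free
fraction measured per subject).

Conventional analysis fits each time-activity curve (TAC) separately by
weighted nonlinear least squares and feeds the point estimates into a
univariate group-level model. For this tracer that pipeline is fragile:
direct estimation of $BP_{ND}$ from rate constants is notoriously
error-prone, the raphe nuclei — the region of principal interest, where the
receptor acts as an autoreceptor — is small and noisy, and the choice of
outcome measure ($BP_{ND}$, $BP_P$, $BP_F$) has historically changed the
conclusions of group comparisons.

This package implements the alternative: a joint hierarchical multivariate
Bayesian model in which all TACs of all subjects are fitted simultaneously,
pooling information across individuals, regions and curves, exploiting the
correlation structure among the kinetic parameters, and drawing group
inference inside the same model. A companion parameter-level model applies
the same hierarchical multivariate structure to SRTM parameters estimated
by NLS when a reference-region (arterial-free) analysis is wanted.

## The joint model

For TAC $(i,j)$ (subject $i$, region $j$) the five log kinetic parameters
$\theta_{ij}$ are modelled as

$$\theta_{ij} = \mu + \rho_j + \eta_i + \beta\,x_{ij} + \varepsilon_{ij},$$

where $\mu$ holds global intercepts (for log BP, per-region means take the
place of a global intercept), $\rho_j$ are pooled region deviations,
$\eta_i \sim \mathcal N_5(0, \Sigma_{\text{ind}})$ are individual
deviations *correlated across the five parameters*, and
$\varepsilon_{ij}$ is a TAC-level deviation with per-parameter SDs.
Covariates enter as fixed effects: sex and age on log $K_1$ and log
$V_{ND}$; region means, sex, age and a group-by-region interaction on
log BP. Group contrasts (non-reference group × region) carry a
$\mathcal N(0, 0.2)$ prior on the log scale, which assigns about 64% prior
mass to group differences below 20%, 81% below 30%, and 9% to increases
beyond 30% (`prior_tail_probability()`).

The observation model links $\theta_{ij}$ to the frame data through the
2TCM: the model curve is the convolution of the two-exponential impulse
response with the (piecewise-linear) arterial input plus a $v_B$-weighted
whole-plasma term, averaged over each frame. Frame $f$ of TAC $(i,j)$ is
Gaussian with SD $\sigma_j\,\bar y_{ij} / w_{ijf}$: $\sigma_j$ is a
per-region dimensionless error scale, $\bar y_{ij}$ the TAC's mean level
(absorbing cross-subject differences in injected dose and input amplitude),
and $w_{ijf}$ the conventional count-based weight
(`compute_weights()`: square root of frame duration times the
decay-uncorrected frame value, normalized to mean one). A Student-t
($\nu = 4$) observation family is available via
`hier_model_spec(obs_family = "student_t")`; the Gaussian default keeps
the error-scale updates conjugate.

Outcome modes: `BPND` parameterizes specific binding as $\log BP_{ND}$;
`BPP` as $\log BP_P$; `BPF` scales each subject's input function by the
measured $f_P$ and parameterizes $\log(K_1/f_P)$, $\log(V_{ND}/f_P)$,
$\log BP_F$. In `BPF` mode the intercept priors are re-centred by the
cohort mean $\log f_P$, since the scaled parameters live $-\log f_P$ above
their physiological scale.

### Priors

* Group contrasts on log BP: $\mathcal N(0, 0.2)$ — exactly, since the
  implied prior tail probabilities are part of the model's interpretation.
* Global intercepts: moderately informative normals,
  $\mathcal N(\log 0.1, 0.25)$ for $\log K_1$,
  $\mathcal N(\log 0.5, 0.5)$ for $\log V_{ND}$,
  $\mathcal N(\log 1, 1)$ for the log BP region means,
  $\mathcal N(\log 0.05, 0.5)$ for $\log k_4$ and $\log v_B$;
  sex/age coefficients $\mathcal N(0, 0.25)$. All exposed in
  `prior_spec()`.
* Hierarchy SDs (TAC-level, pooled region, random slopes): half-normal
  with scale 0.3.
* $\Sigma_{\text{ind}}$: inverse-Wishart (df 7, scale $0.1 I$). We chose
  the inverse-Wishart over a separated SD + correlation (LKJ-type) prior
  deliberately: it makes the individual-level covariance draw conjugate,
  which is what keeps the blocked Gibbs sampler practical on a single CPU.
  The prior is weak at the sample sizes involved, and posterior correlation
  matrices are reported via `omega_mean()` after a variance/correlation
  decomposition of the draws.
* Observation variances: vague inverse-gamma (conjugate under the Gaussian
  family).

### Sampling

No general-purpose MCMC backend would help here — the likelihood couples a
compartment-model solver to every one of hundreds of latent parameter
vectors — so the package ships its own blocked
Metropolis-within-Gibbs sampler:

1. **Per-TAC Metropolis.** Each $\theta_{ij}$ (5 dimensions) is updated by
   an adaptive multivariate random walk against the compiled 2TCM
   likelihood. Proposal covariances adapt during warmup to the
   *conditional* residuals $\theta_{ij} - m_{ij}$, so they match the
   conditional posterior rather than the wandering marginal.
2. **Conjugate Gibbs** for individual deviations, fixed effects, pooled
   region deviations and random slopes, $\Sigma_{\text{ind}}$
   (inverse-Wishart) and, under the Gaussian family, the observation
   variances. Hierarchy SDs use slice sampling on the log scale under their
   half-normal priors.
3. **Location-shift Metropolis moves.** The 2TCM likelihood is nearly flat
   along two directions — $\log BP$ up / $\log V_{ND}$ down at fixed
   $BP_P$ (and almost fixed $V_T$), and $\log K_1$ / $\log V_{ND}$ together
   at fixed $k_2$ — and along any direction that translates a whole
   hierarchy level. Dedicated Metropolis moves translate all per-TAC values
   of a parameter together with the corresponding intercept (globally, per
   region, or per subject with the individual deviation), including the
   paired ridge directions. Without these moves the chains take a very long
   time to traverse the ridge; with them the location mixes in hundreds of
   sweeps.
4. **Interweaving draws.** Conditional on $\theta$, the split between a
   fixed effect and its compensating pooled deviations (intercept vs
   $\eta$, intercept vs $\rho$, sex/age coefficients vs $\eta$) is
   likelihood-invariant, so it is resampled *exactly* from the priors —
   a Gaussian draw along each invariant direction. This removes the classic
   slow alternation between regression coefficients and random effects.

We use this centred parameterization with interweaving rather than the
non-centred parameterization common in Hamiltonian Monte Carlo
implementations: non-centring helps gradient-based samplers, whereas for
blocked Gibbs the centred form keeps every conditional conjugate and the
interweaving draws supply the missing mixing.

Chains are initialized from a fast two-start NLS fit of each TAC.
Convergence is summarized by split-$\hat R$ and a crude effective sample
size on all scalar parameters; any fixed effect with $\hat R > 1.05$
triggers a recorded warning. Defaults (`hier_model_spec()`): 2 chains,
400 warmup + 400 sampling sweeps — intentionally modest presets sized for
the reduced-scale analyses in this package's tests; real analyses should
use 4 chains and several thousand sweeps and check the diagnostics.

Model evaluation inside the sampler runs on a thinned time grid (1-second
spacing over the input peak, 0.5 min beyond 10 min). The quadrature itself
is exact per linear segment (see below); the only approximation is the
linear interpolation of the input between grid points, which is orders of
magnitude below frame noise.

## Kinetic forward models

`simulate_2tc_tac()` solves the 2TCM by exact convolution of its
biexponential impulse response with a piecewise-linear input — per linear
segment the update and its time-integral have closed forms built from the
stable kernels $E_0(x) = (1-e^{-x})/x$, $E_1 = (1-E_0)/x$,
$E_2 = (1/2-E_1)/x$ with series expansions for small $x$ — rather than a
generic ODE stepper. This is exact for the class of inputs the package
uses, fast enough to sit inside MCMC, and testable against closed-form
solutions (the package's tests verify agreement with an independent ODE
solver at $10^{-5}$ relative error and with analytic solutions at
$10^{-6}$).

Frame values are *time averages* of the model curve over each frame
(integral divided by duration), matching how scanners bin counts; this
matters for the early 20-second frames. The default schedule is 20 frames
over 110 minutes: $3 \times 20$ s, $3 \times 1$, $3 \times 2$,
$2 \times 5$, $9 \times 10$ min.

Inputs are interpolated piecewise-linearly, are zero before time zero, and
are never extrapolated beyond their last sample — a schedule extending past
the input support is an error naming the uncovered interval.

`simulate_srtm_tac()` implements the simplified reference tissue model
$C_T = R_1 C_{ref} + (k_2 - R_1 k_{2a})\,(C_{ref} \otimes e^{-k_{2a}t})$
with the same machinery (single exponential).

## The synthetic cohort

No public dataset exists for this tracer with full arterial input and
$f_P$ measurement, so validation rests on a synthetic cohort generator
(`generate_cohort()`) with known ground truth. Its defaults emulate the
study design the package targets:

* three groups — healthy volunteers (HV, $n=57$), not-recently-medicated
  (NRM, $n=50$) and antidepressant-exposed (AE, $n=53$) patients;
* eight regions (DLPFC, MPFC, ACC, PCC, hippocampus, amygdala, insula,
  raphe nuclei), optionally cerebellar grey/white matter; region-level
  geometric means chosen as plausible values for a serotonin-1A antagonist
  ligand (high cortical/limbic $BP_{ND}$ of 3.5–5.5, raphe 2.5, cerebellar
  white matter 0.08);
* correlated individual-level log-parameter deviations
  ($\Omega$ with moderate positive correlations, SDs 0.10–0.20) plus
  TAC-level deviations (SDs 0.03–0.08);
* a group effect on log BP concentrated in the raphe:
  NRM−HV $= \log 1.15$ in RN and $\log 1.075$ (half on the log scale) in
  projection regions — a small effect by design, consistent with a
  standardized effect size around 0.3;
* $f_P$ log-normal around 0.07 (SD on the log scale 0.25), with optional
  group shifts and/or deterministic measurement drift over the study
  period; the `drift_confound` preset (staggered recruitment + a 30%
  linear decline, no true group difference) reproduces the confounding
  pattern in which a spurious $f_P$ group difference appears and is
  absorbed by a thin-plate-spline drift term;
* a tri-exponential arterial input template with linear rise to a 1-min
  peak, per-subject log-normal jitter, and a whole-plasma curve derived
  from a declining parent fraction;
* additive Gaussian frame noise with SD proportional to the TAC mean and
  inversely proportional to the NLS weight, scaled per region — a factor 3
  for the raphe nuclei, which is what makes conventional raphe
  quantification unreliable. The `high_noise` preset (base level 0.15,
  i.e. late-frame SDs approaching half the TAC mean in the raphe) defines
  the low-count condition used for the shrinkage analyses.

What the generator does *not* emulate: radiometabolite contamination,
scanner resolution and partial-volume effects, motion, or non-Gaussian
count statistics. Passing recovery tests on this cohort therefore
demonstrates correctness of the estimation machinery under a well-specified
model, not robustness to every artefact of real data.

The cerebellar elevation used by `indirect_bpnd_bias_probe()` raises
cerebellar log $V_T$ in the patient groups (applied through $V_{ND}$,
since cerebellar $BP_{ND}$ is too small for a specific-binding shift alone
to move $V_T$ appreciably); the probe then quantifies the downward bias
this induces in indirect (reference-tissue) $BP_{ND}$ group contrasts —
the sign is forced analytically by $BP_{ND} = V_T/V_{ref} - 1$, and the
magnitude grows monotonically with the elevation.

## The comparison arms

* `fit_2tc_nls()` / `fit_srtm_nls()`: conventional weighted NLS per TAC,
  box-constrained quasi-Newton refinement from a fixed grid of eight
  starting points (robustness without randomness); non-convergence is
  flagged, never thrown. Weight handling clamps negative frame values at
  zero before decay un-correction (frame midpoint convention).
* `fit_pumba()`: the parameter-level hierarchical model for SRTM estimates
  — same fixed-effect structure and priors, trivariate correlated
  individual deviations and (by default) correlated residuals, fully
  conjugate Gibbs. Whether the residual should be correlated or
  independent per parameter is genuinely open; we default to correlated
  and expose `residual_correlated = FALSE`.
* `fit_lme_logbp()`: the univariate mixed-model arm,
  `log BP ~ region + sex + age + group:region + (1 | subject)` by REML.
* `fp_group_anova()` and `fp_drift_model()`: one-way ANOVA of $\log f_P$
  with Tukey-adjusted pairwise percent differences (whether the original
  pairwise tests were multiplicity-adjusted is unstated; Tukey is the
  default and `adjust = "none"` is exposed), and the penalized
  thin-plate-spline drift model (basis dimension 10, REML smoothing).

## Inference utilities

`summarize_contrast()` transforms contrast draws to percent differences
draw-wise before taking quantiles (identical to transforming the quantiles
for monotone maps, but stated once and used everywhere), reports 80% and
95% intervals and directional probabilities with the tie convention
$P(\beta>0) = \text{mean}(\beta>0) + 0.5\,\text{mean}(\beta=0)$ so the
degenerate all-zero case is well defined. `power_sample_size()` inverts the
noncentral-t power function by integer bisection (two-sided $\alpha$);
`probability_of_superiority()` is $\Phi(d/\sqrt 2)$.
`extract_individual_effects()` returns the partially pooled
individual-level (random-effect) posterior means; for cross-model
comparison of $BP_P$ it maps each mode's deviations onto a common scale
($V_{ND}$ + $BP_{ND}$ deviations in `BPND` mode; $BP_F$ deviation plus
centred $\log f_P$ in `BPF` mode).

## Numerical choices and degenerate inputs

* Convolution kernels switch to series below $x = 10^{-8}$–$10^{-2}$
  (per kernel) so no catastrophic cancellation occurs for slow rate
  constants and short frames.
* TAC-level SDs are floored at $10^{-4}$ inside the sampler so degenerate
  (zero-variance) cohorts remain fittable.
* $\log v_B$ is hard-bounded above at $\log 0.4$ in the sampler.
* All-zero TACs make the count-based weights degenerate and are an error.
* A repeated eigenvalue of the 2TCM system matrix (a measure-zero
  parameter set) is perturbed by $10^{-9}$ rather than special-cased.
* Every stochastic entry point takes an explicit integer seed; cohort
  generation is bit-reproducible from `(config, seed)`.

## Problem sizes used in the tests

The checks in `tests/` and `scripts/acceptance.R` run the full machinery
at deliberately reduced scale, chosen as the smallest sizes at which each
property is meaningfully testable: the shrinkage comparison uses the
`high_noise` preset with 20 subjects × 8 regions and 2 chains × (500+500)
sweeps; the $f_P$-invariance comparison 16–24 subjects × 6 regions
(the correlation of individual BP$_P$ effects across parameterizations is
itself attenuated by per-subject estimation error, so it approaches its
large-sample value only as the reduced cohort grows); recovery
and subgroup analyses 10–21 subjects over 2–4 regions; the
parameter-level calibration 20 independent null fits of 30 subjects each.
A real analysis at full cohort size (160 subjects × 8 regions) uses the
same code path with longer chains.

## Known limitations

* The joint model supports arterial-input 2TCM quantification only;
  reference-tissue data enter through the parameter-level model after NLS.
* One error scale per region (scaled by TAC mean) is a simplification;
  per-TAC error scales are not estimated.
* $f_P$ enters as a scalar multiplying the input; in-scan dynamics of
  plasma protein binding are not modelled.
* The inverse-Wishart covariance prior ties variances and correlations
  weakly together; at very small $n$ its shrinkage of correlations toward
  zero is noticeable (the correlation-recovery tests quantify this).
* Posterior summaries at the reduced sampler presets carry visible Monte
  Carlo error; the $\hat R$ diagnostics must be consulted before trusting
  any single fit.
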