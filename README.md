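# hbpet — hierarchical multivariate Bayesian quantification of PET time-activity curves

`hbpet` is an R package for quantifying dynamic PET data with the
two-tissue compartment model (2TCM) and drawing group-level inference in a
single joint hierarchical multivariate Bayesian model, instead of the
conventional two-stage pipeline (per-curve nonlinear least squares followed
by a univariate group test). It is aimed at researchers analysing
radioligands — such as serotonin-1A antagonist tracers — for which direct
estimation of binding potential from rate constants is noisy, the region of
interest (the raphe nuclei) is small and high-variance, and conclusions
have historically depended on the choice of outcome measure
(BP<sub>ND</sub>, BP<sub>P</sub> or BP<sub>F</sub>).

## The model

For each time-activity curve (TAC) of subject *i* in region *j*, the five
log kinetic parameters θ<sub>ij</sub> = (log K₁, log V<sub>ND</sub>,
log BP, log k₄, log v<sub>B</sub>) follow

θ<sub>ij</sub> = μ + ρ<sub>j</sub> + η<sub>i</sub> + β x<sub>ij</sub> + ε<sub>ij</sub>,

with pooled region deviations ρ<sub>j</sub>, individual deviations
η<sub>i</sub> ~ N₅(0, Σ<sub>ind</sub>) *correlated across parameters*,
TAC-level deviations ε<sub>ij</sub>, and fixed effects x<sub>ij</sub>
(sex and age on log K₁ and log V<sub>ND</sub>; region means, sex, age and
group-by-region contrasts on log BP). Group contrasts carry a
Normal(0, 0.2) prior on the log scale — about 64% prior mass on group
differences below 20% and 9% on increases beyond 30%. The data enter
through the 2TCM itself: every frame of every TAC contributes a likelihood
term through the frame-averaged model curve, so quantification and group
inference happen in one model and poorly identified parameters borrow
strength across the cohort. Outcomes can be parameterized as
BP<sub>ND</sub> = k₃/k₄, BP<sub>P</sub> = V<sub>ND</sub>·BP<sub>ND</sub>,
or BP<sub>F</sub> = BP<sub>P</sub>/f<sub>P</sub> (with the arterial input
scaled by the measured plasma free fraction).

Because the likelihood couples a compartment-model solver to hundreds of
latent parameter vectors, the package ships its own blocked
Metropolis-within-Gibbs sampler (adaptive per-TAC Metropolis against a
compiled exact-convolution 2TCM likelihood, conjugate Gibbs for the
hierarchy, dedicated ridge/location moves and exact interweaving draws;
see the methods vignette in `vignettes/`). Also included:

* `fit_pumba()` — the same hierarchical multivariate structure applied to
  SRTM parameters estimated per curve by weighted NLS (for
  reference-tissue, arterial-free analyses);
* `fit_2tc_nls()`, `fit_srtm_nls()` — conventional weighted NLS
  quantification (the comparison arm);
* `fit_lme_logbp()`, `fp_group_anova()`, `fp_drift_model()` — the
  univariate mixed model on log BP, the plasma-free-fraction group ANOVA
  and the penalized thin-plate-spline drift model;
* `generate_cohort()` — a fully synthetic study generator with known
  ground truth (three groups 57/50/53, eight regions, 20-frame/110-min
  schedule, correlated individual effects, raphe-concentrated group
  effects, f<sub>P</sub> drift scenarios, region-dependent noise worst in
  the raphe);
* `summarize_contrast()`, `extract_individual_effects()`,
  `power_sample_size()`, `probability_of_superiority()` — posterior and
  analytic summaries.

## Worked example

```r
library(hbpet)

# what the group-difference prior means
round(100 * prior_tail_probability(0.2, 20, "two_sided_within"))  # 64
round(100 * prior_tail_probability(0.2, 30, "two_sided_within"))  # 81

# a small synthetic study: 6 HV + 6 NRM subjects, three regions,
# a +15% raphe (RN) binding effect in the NRM group
cfg <- cohort_config(n_hv = 6, n_nrm = 6, n_ae = 0,
                     regions = c("DLPFC", "HIP", "RN"))
cohort <- generate_cohort(cfg, seed = 42)

spec <- hier_model_spec(chains = 2, warmup = 250, iter = 250)  # demo preset
fit <- fit_hier(cohort, spec, seed = 7)
summarize_contrast(fit, "NRM-HV:RN")
#>   contrast  pct_diff  lo95  lo80  hi80  hi95 p_gt0 p_lt0
#> 1 NRM-HV:RN      9.4 -6.63 -1.27  25.9  37.9 0.862 0.138
```

The posterior median of the NRM−HV raphe contrast is +9.4% (the
generating effect was +15%; this small simulated cohort happened to
realize less), with an 86% posterior probability that the difference is
positive — at only six subjects per group the direction is suggestive,
not conclusive. At these demonstration chain lengths the fit
records an R-hat warning for some fixed effects; real analyses should use
4 chains and a few thousand sweeps.

```r
# sample size for a conventional t-test at the small effect sizes
# typical of this application (Cohen's d = 0.32)
power_sample_size(d = 0.32, alpha = 0.05, power = 0.8)$n_per_group
#> [1] 155
round(100 * probability_of_superiority(0.32), 1)
#> [1] 59
```

That is: detecting a d = 0.32 group difference with a plain two-sample
t-test needs about 155 subjects *per group*, and a randomly chosen patient
exceeds a randomly chosen control only 59% of the time — which is why the
joint model's efficiency matters.

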