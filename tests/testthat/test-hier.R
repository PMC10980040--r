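test_that("a near-degenerate cohort is recovered without spurious group effects", {
  # all between-individual variation switched off and minimal noise: the
  # posterior should sit on the generating means and group intervals must
  # cover zero
  cfg <- cohort_config(
    n_hv = 4, n_nrm = 4, n_ae = 0, regions = c("DLPFC", "RN"),
    tau_ind = rep(0, 5), sigma_tac = rep(0.01, 5), noise_base = 0.01,
    beta_age_k1 = 0, beta_age_vnd = 0, beta_sex_k1 = 0,
    delta_rn = 0, delta_proj = 0
  )
  coh <- generate_cohort(cfg, seed = 17)
  spec <- hier_model_spec(chains = 2, warmup = 250, iter = 250)
  fit <- suppressWarnings(fit_hier(coh, spec, seed = 2))
  dm <- draws_matrix(fit)
  rt <- cfg$region_table
  for (rg in cfg$regions) {
    est <- dm[, paste0("bp_mean[", rg, "]")]
    expect_lt(abs(mean(est) - log(rt$BPND[rt$region == rg])), 0.1)
    s <- summarize_contrast(fit, paste0("NRM-HV:", rg))
    expect_lt(s$lo95, 0)
    expect_gt(s$hi95, 0)
  }
  # region-level K1 (intercept + pooled region deviation) matches the
  # generating value; the intercept alone is only identified jointly with
  # the deviations
  k1_dlpfc <- dm[, "K1_int"] + dm[, "r[DLPFC,K1]"]
  expect_lt(abs(mean(k1_dlpfc) - log(rt$K1[rt$region == "DLPFC"])), 0.1)
})

test_that("a raphe-concentrated group effect is recovered with high directional probability", {
  rec <- recovery_fixture()
  coh <- rec$cohort
  fit <- rec$fit
  s <- summarize_contrast(fit, "NRM-HV:RN")
  # the posterior interval covers the generating effect; at two dozen
  # subjects under the default raphe noise the direction is identified as
  # probable, not conclusive
  truth_pct <- 100 * (exp(log(1.15)) - 1)
  expect_gt(s$hi95, truth_pct)
  expect_lt(s$lo95, truth_pct)
  expect_gt(s$p_gt0, 0.75)

  # univariate LME on the per-TAC NLS estimates: intervals should be wider
  # than the joint model's for the same contrast
  nls <- fit_nls_cohort(coh, model = "2tc", mode = "BPND")
  bp <- nls[nls$parameter == "log_BPND", ]
  dat <- data.frame(
    subject_id = bp$subject_id, region = bp$region,
    group = coh$subjects$group[match(bp$subject_id, coh$subjects$subject_id)],
    sex = coh$subjects$sex[match(bp$subject_id, coh$subjects$subject_id)],
    age = coh$subjects$age[match(bp$subject_id, coh$subjects$subject_id)],
    log_bp = bp$estimate
  )
  lme <- fit_lme_logbp(dat)
  ct <- lme$contrasts[lme$contrasts$contrast == "NRM-HV:RN", ]
  expect_gt(ct$hi95 - ct$lo95, s$hi95 - s$lo95)
})

test_that("the RN-versus-projection contrast model identifies a 2x raphe effect", {
  coh <- recovery_fixture()$cohort
  spec <- hier_model_spec(chains = 2, warmup = 400, iter = 400)
  fit <- suppressWarnings(fit_region_contrast_model(coh, spec, seed = 4))
  expect_true(all(c("NRM-HV:RN", "NRM-HV:proj") %in% fit$contrast_names))
  p_rn_gt_proj <- contrast_difference_probability(fit, "NRM-HV:RN",
                                                  "NRM-HV:proj")
  expect_gt(p_rn_gt_proj, 0.7)
  # projection effects are homogeneous by construction, so the random-slope
  # SD concentrates near zero
  dm <- draws_matrix(fit)
  expect_lt(mean(dm[, "slope_sd[NRM]"]), 0.1)
})

test_that("BP_P posteriors agree between the BPND-mode and BPP-mode parameterizations", {
  cfg <- cohort_config(n_hv = 5, n_nrm = 0, n_ae = 0,
                       regions = c("DLPFC", "RN"), noise_base = 0.01)
  coh <- generate_cohort(cfg, seed = 29)
  spec_nd <- hier_model_spec(mode = "BPND", chains = 1, warmup = 400,
                             iter = 800)
  spec_pp <- hier_model_spec(mode = "BPP", chains = 1, warmup = 400,
                             iter = 800)
  fit_nd <- suppressWarnings(fit_hier(coh, spec_nd, seed = 5))
  fit_pp <- suppressWarnings(fit_hier(coh, spec_pp, seed = 6))
  # per-TAC posterior-mean log BP_P from each parameterization; the mean
  # relative deviation is held to 5%, individual noisy raphe TACs carry
  # extra Monte Carlo spread
  bpp_nd <- fit_nd$theta_postmean[, "log_VND"] + fit_nd$theta_postmean[, "log_BPND"]
  bpp_pp <- fit_pp$theta_postmean[, "log_BPP"]
  rel <- abs(exp(bpp_nd) - exp(bpp_pp)) / exp(bpp_pp)
  expect_lt(mean(rel), 0.05)
  expect_lt(max(rel), 0.12)
})

test_that("subgroup fits recover a shared correlation structure", {
  cfg <- cohort_config(n_hv = 7, n_nrm = 7, n_ae = 7,
                       regions = c("DLPFC", "HIP", "RN"), noise_base = 0.04)
  coh <- generate_cohort(cfg, seed = 31)
  spec <- hier_model_spec(chains = 1, warmup = 250, iter = 250)
  oms <- list()
  for (g in c("HV", "NRM", "AE")) {
    f <- suppressWarnings(fit_subgroup(coh, g, spec, seed = 7))
    # single-group fits drop group fixed effects entirely
    expect_equal(length(f$contrast_names), 0)
    oms[[g]] <- omega_mean(f)
  }
  cmp <- compare_correlation_matrices(oms)
  expect_lt(max(cmp$max_abs_diff), 0.5)
  # shared-truth comparison: closer than a constructed strong difference
  strong <- oms$HV
  strong[1, 2] <- strong[2, 1] <- min(0.99, strong[1, 2] + 0.6)
  cmp2 <- compare_correlation_matrices(list(a = oms$HV, b = strong))
  expect_lt(median(cmp$max_abs_diff), cmp2$max_abs_diff[1])
  expect_error(fit_subgroup(coh, "none", spec), "at least 3 subjects")
})

test_that("the sampler records convergence diagnostics and flags poor mixing", {
  fit <- small_fit()
  expect_true(all(c("parameter", "rhat", "ess") %in% names(fit$diagnostics)))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  # rhat warnings, when any, name fixed effects
  expect_type(fit$rhat_warnings, "character")
})
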