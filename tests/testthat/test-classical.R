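test_that("the one-way ANOVA matches the hand-computed fixture", {
  # groups {1,2}, {3,4}, {5,6} on already-logged values:
  # SSB = 2*((1.5-3.5)^2 + 0 + (5.5-3.5)^2) = 16 on 2 df, MSB = 8;
  # SSW = 6 * 0.25 = 1.5 on 3 df, MSW = 0.5; F = 16
  subj <- data.frame(group = rep(c("A", "B", "C"), each = 2),
                     log_fp = c(1, 2, 3, 4, 5, 6))
  out <- fp_group_anova(subj)
  expect_equal(out$F, 16)
  expect_equal(out$df, c(2, 3))
  expect_equal(nrow(out$pairwise), 3)
  # percent transform of the log differences
  ba <- out$pairwise[out$pairwise$comparison == "B-A", ]
  expect_equal(ba$pct_diff, 100 * (exp(2) - 1))

  # all groups identical -> F = 0
  subj0 <- data.frame(group = rep(c("A", "B", "C"), each = 3),
                      log_fp = rep(c(1, 2, 3), 3))
  expect_equal(fp_group_anova(subj0)$F, 0, tolerance = 1e-12)

  expect_error(fp_group_anova(data.frame(group = "A", log_fp = 1)),
               "at least 2 groups")
})

test_that("ANOVA type-I error is calibrated at the nominal level", {
  set.seed(99)
  reps <- 2000
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    subj <- data.frame(group = rep(c("HV", "NRM", "AE"), each = 20),
                       log_fp = rnorm(60))
    rej[r] <- fp_group_anova(subj)$p < 0.05
  }
  expect_gt(mean(rej), 0.04)
  expect_lt(mean(rej), 0.06)
})

test_that("the LME reduces to OLS when the random-intercept variance vanishes", {
  set.seed(5)
  n <- 40
  dat <- expand.grid(subject_id = sprintf("s%02d", 1:n),
                     region = c("A", "B", "C"), stringsAsFactors = FALSE)
  subj_group <- setNames(rep(c("HV", "NRM"), each = n / 2),
                         sprintf("s%02d", 1:n))
  subj_sex <- setNames(sample(c("F", "M"), n, TRUE), sprintf("s%02d", 1:n))
  subj_age <- setNames(runif(n, 20, 60), sprintf("s%02d", 1:n))
  dat$group <- subj_group[dat$subject_id]
  dat$sex <- subj_sex[dat$subject_id]
  dat$age <- subj_age[dat$subject_id]
  # pure fixed-effect data with iid noise: no subject-level variance
  dat$log_bp <- 1 + 0.2 * (dat$region == "B") + 0.1 * (dat$group == "NRM") +
    rnorm(nrow(dat), 0, 0.1)
  res <- fit_lme_logbp(dat)
  ols <- lm(log_bp ~ region + sex + age + group:region,
            data = transform(dat,
                             group = factor(group, c("HV", "NRM")),
                             region = factor(region)))
  common <- intersect(res$fixef$term, names(coef(ols)))
  expect_gt(length(common), 5)
  expect_lt(max(abs(res$fixef$estimate[match(common, res$fixef$term)] -
                      coef(ols)[common])), 1e-6)
})

test_that("the LME exactly recovers effects from balanced noiseless data", {
  dat <- expand.grid(subject_id = sprintf("s%02d", 1:20),
                     region = c("A", "B"), stringsAsFactors = FALSE)
  dat$group <- ifelse(as.integer(sub("s", "", dat$subject_id)) <= 10,
                      "HV", "NRM")
  dat$sex <- "F"; dat$age <- 40
  dat$log_bp <- 2 + 0.5 * (dat$region == "B") +
    0.15 * (dat$group == "NRM") * (dat$region == "B") +
    0.25 * (dat$group == "NRM") * (dat$region == "A")
  # exactly deterministic data: the optimizer grumbles but the estimates
  # are exact
  res <- suppressWarnings(fit_lme_logbp(dat))
  ct <- res$contrasts
  expect_equal(ct$estimate[ct$contrast == "NRM-HV:B"], 0.15, tolerance = 1e-8)
  expect_equal(ct$estimate[ct$contrast == "NRM-HV:A"], 0.25, tolerance = 1e-8)
  expect_type(res$singular, "logical") # degenerate fits are flagged, never thrown
})

test_that("the drift model penalizes an absent smooth to near-linearity", {
  set.seed(11)
  n <- 200
  subj <- data.frame(group = rep(c("HV", "NRM"), each = n / 2),
                     scan_date = runif(n, 0, 3650),
                     log_fp = rnorm(n, log(0.07), 0.2))
  res <- fp_drift_model(subj)
  expect_lt(res$smooth_edf, 2.5)
  expect_gt(res$group_p, 0.05)
  expect_lte(res$smooth_edf, res$basis_dim - 1)
  expect_error(fp_drift_model(transform(subj, scan_date = 1)), "identical")
})

test_that("a known injected drift is recovered within the pointwise band", {
  set.seed(12)
  n <- 300
  dates <- runif(n, 0, 3650)
  smooth_true <- function(d) 0.3 * sin(2 * pi * d / 3650) - 0.2 * d / 3650
  subj <- data.frame(group = "HV", scan_date = dates,
                     log_fp = log(0.07) + smooth_true(dates) + rnorm(n, 0, 0.1))
  res <- fp_drift_model(subj)
  expect_lt(res$smooth_p, 1e-4)
  grid <- res$smooth_grid
  truth_c <- smooth_true(grid$scan_date) -
    mean(smooth_true(grid$scan_date))
  fitted_c <- grid$smooth - mean(grid$smooth)
  # pointwise agreement well inside the noise level
  expect_lt(max(abs(fitted_c - truth_c)), 0.1)
})

test_that("a drift-induced spurious group effect is absorbed by the smooth term", {
  # staggered recruitment plus measurement drift with no true group effect:
  # the ANOVA flags a group difference, the drift-adjusted model does not
  hits_anova <- 0
  hits_gam <- 0
  reps <- 50
  for (r in seq_len(reps)) {
    cfg <- cohort_preset("drift_confound", n_hv = 40, n_nrm = 40, n_ae = 0)
    coh <- generate_cohort(cfg, seed = 100 + r, simulate_tacs = FALSE)
    s <- coh$subjects
    a <- fp_group_anova(s)
    g <- fp_drift_model(s)
    if (a$p < 0.05) hits_anova <- hits_anova + 1
    if (g$group_p < 0.05) hits_gam <- hits_gam + 1
  }
  expect_gt(hits_anova, reps / 2)  # spurious effect usually detected...
  expect_lt(hits_gam, hits_anova / 2)  # ...and usually absorbed by the smooth
})
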