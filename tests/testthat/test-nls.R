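test_that("frame weights follow the decay-uncorrected count formula", {
  # 10-min frame centred at t = 100 min, decay-corrected conc 1.0:
  # uncorrected conc = 2^(-100/20.364), weight = sqrt(10 * that)
  w <- compute_weights(95, 10, 1.0, half_life = 20.364, normalize = FALSE)
  expect_equal(w, sqrt(10 * 2^(-100 / 20.364)), tolerance = 1e-12)
  expect_equal(round(w, 3), 0.577)

  # equal duration and equal uncorrected concentration -> equal weights:
  # conc rising exactly with decay across frames cancels the correction
  fs <- c(0, 10); fd <- c(10, 10)
  conc <- 2^((fs + 5) / 20.364)
  w2 <- compute_weights(fs, fd, conc)
  expect_equal(w2[1], w2[2], tolerance = 1e-12)

  expect_error(compute_weights(c(0, 10), c(10, -1), c(1, 1)), "positive")
  expect_error(compute_weights(c(0, 10), c(10, 10), c(0, 0)), "degenerate")
  # negative frame values are clamped to zero, not propagated
  w3 <- compute_weights(c(0, 10), c(10, 10), c(-0.5, 1), normalize = FALSE)
  expect_equal(w3[1], 0)
})

test_that("weighted NLS recovers noiseless 2TCM parameters across a grid", {
  sch <- default_frame_schedule()
  coh <- small_cohort()
  inp <- coh$inputs[[1]]
  grid <- expand.grid(K1 = c(0.06, 0.12), BPND = c(0.5, 4), k4 = c(0.02, 0.06))
  for (i in seq_len(nrow(grid))) {
    p <- twotc_params(grid$K1[i], 0.45, grid$BPND[i], grid$k4[i], 0.05)
    tac <- simulate_2tc_tac(p, inp, sch)
    fit <- fit_2tc_nls(tac, inp)
    expect_true(fit$converged)
    truth <- c(p$log_K1, p$log_VND, p$log_BPND, p$log_k4, p$log_vB)
    expect_lt(max(abs(fit$estimate - truth)), 1e-3)
  }
})

test_that("BPND, BPP and BPF parameterizations give one fitted curve", {
  coh <- small_cohort()
  sch <- coh$config$schedule
  tt <- coh$tacs[coh$tacs$subject_id == "s002" & coh$tacs$region == "DLPFC", ]
  tac <- tissue_tac(tt$conc, sch)
  inp <- coh$inputs[["s002"]]
  fP <- coh$subjects$fP_measured[coh$subjects$subject_id == "s002"]
  f_nd <- fit_2tc_nls(tac, inp, mode = "BPND")
  f_pp <- fit_2tc_nls(tac, inp, mode = "BPP")
  f_bf <- fit_2tc_nls(tac, inp, mode = "BPF", fP = fP)
  expect_lt(max(abs(f_nd$fitted - f_pp$fitted)), 1e-4 * max(f_nd$fitted))
  expect_lt(max(abs(f_nd$fitted - f_bf$fitted)), 1e-4 * max(f_nd$fitted))
  # identical implied micro-parameters
  expect_equal(unname(f_pp$estimate["log_BPP"]),
               unname(f_nd$estimate["log_VND"] + f_nd$estimate["log_BPND"]),
               tolerance = 1e-3)
  expect_equal(unname(f_nd$log_BPND), unname(f_pp$log_BPND), tolerance = 1e-3)
  # BPF estimates are the f_P-scaled quantities
  expect_equal(unname(f_bf$estimate["log_K1"]),
               unname(f_nd$estimate["log_K1"]) - log(fP), tolerance = 1e-2)
})

test_that("NLS matches a coarse grid-search oracle on a noisy raphe TAC", {
  coh <- small_cohort()
  sch <- coh$config$schedule
  tt <- coh$tacs[coh$tacs$subject_id == "s003" & coh$tacs$region == "RN", ]
  tac <- tissue_tac(tt$conc, sch)
  inp <- coh$inputs[["s003"]]
  fit <- fit_2tc_nls(tac, inp)
  w <- compute_weights(sch$frame_start, sch$frame_dur, tt$conc)
  g <- hbpet:::sim_grid(inp, sch)
  sse <- function(th) {
    mu <- hbpet:::.tac_2tc_frames(g$time, g$cp, g$wpI, g$istart, g$iend,
                                  exp(th[1]), exp(th[2]), exp(th[3]),
                                  exp(th[4]), exp(th[5]))
    sum((w * (tt$conc - mu))^2)
  }
  # brute-force enumeration over a coarse but wide log-parameter grid
  oracle <- Inf
  for (lk1 in log(c(0.04, 0.06, 0.09, 0.13)))
    for (lvnd in log(c(0.2, 0.4, 0.7)))
      for (lbp in log(c(0.5, 1.5, 2.5, 4, 7)))
        for (lk4 in log(c(0.015, 0.03, 0.06)))
          oracle <- min(oracle, sse(c(lk1, lvnd, lbp, lk4, log(0.05))))
  # the optimizer must do at least as well as the best grid point
  expect_lte(fit$rss, oracle * 1.01)
})

test_that("SRTM NLS recovers noiseless parameters and handles the boundary case", {
  sch <- default_frame_schedule()
  tt <- seq(0, 110, 0.05)
  ref <- data.frame(time = tt, conc = 3 * (exp(-0.06 * tt) - exp(-1.2 * tt)))
  sp <- srtm_params(R1 = 0.85, k2prime = 0.16, BPND = 2.2)
  tac <- simulate_srtm_tac(sp, ref, sch)
  fit <- fit_srtm_nls(tac, ref)
  expect_lt(max(abs(fit$estimate -
                      c(sp$log_R1, sp$log_k2prime, sp$log_BPND))), 1e-3)

  # target identical to reference: R1 = 1 and BP_ND at its lower boundary
  ref_tac <- tissue_tac(simulate_srtm_tac(srtm_params(1, 0.16, 1e-12),
                                          ref, sch)$conc, sch)
  fit0 <- fit_srtm_nls(ref_tac, ref)
  expect_lt(abs(fit0$estimate["log_R1"]), 0.01)
  expect_lt(exp(fit0$estimate["log_BPND"]), 0.05)
})

test_that("SRTM NLS matches a grid-search oracle on a noisy TAC", {
  coh <- small_cohort()
  sch <- coh$config$schedule
  tt <- seq(0, 110, 0.05)
  ref <- data.frame(time = tt, conc = 3 * (exp(-0.06 * tt) - exp(-1.2 * tt)))
  sp <- srtm_params(R1 = 0.9, k2prime = 0.15, BPND = 1.8)
  clean <- simulate_srtm_tac(sp, ref, sch)$conc
  set.seed(31)
  w0 <- compute_weights(sch$frame_start, sch$frame_dur, clean)
  noisy <- clean + rnorm(20, 0, 0.12 * mean(clean) / w0)
  tac <- tissue_tac(noisy, sch)
  fit <- fit_srtm_nls(tac, ref)
  w <- fit$weights
  oracle <- Inf
  for (lr1 in log(seq(0.6, 1.3, by = 0.1)))
    for (lk2 in log(c(0.08, 0.12, 0.16, 0.22)))
      for (lbp in log(c(0.6, 1.2, 1.8, 2.6, 4))) {
        mu <- simulate_srtm_tac(srtm_params(exp(lr1), exp(lk2), exp(lbp)),
                                ref, sch)$conc
        oracle <- min(oracle, sum((w * (noisy - mu))^2))
      }
  expect_lte(fit$rss, oracle * 1.01)
})

test_that("cohort-level NLS returns the tidy parameter schema", {
  coh <- small_cohort()
  sub <- coh
  sub$subjects <- coh$subjects[1:2, ]
  sub$tacs <- coh$tacs[coh$tacs$subject_id %in% sub$subjects$subject_id, ]
  sub$inputs <- coh$inputs[sub$subjects$subject_id]
  pt <- fit_nls_cohort(sub, model = "2tc", mode = "BPND")
  expect_equal(sort(unique(pt$parameter)),
               sort(c("log_K1", "log_VND", "log_BPND", "log_k4", "log_vB")))
  expect_equal(nrow(pt), 2 * 3 * 5) # subjects x regions x parameters
  expect_true(all(c("subject_id", "region", "model", "mode", "parameter",
                    "estimate", "se", "converged") %in% names(pt)))
})
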