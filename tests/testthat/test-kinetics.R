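test_that("frame schedule enforces its invariants and the default spans 110 min", {
  sch <- default_frame_schedule()
  expect_equal(nrow(sch), 20)
  expect_equal(sum(sch$frame_dur), 110)
  expect_equal(sch$frame_end[20], 110)
  # contiguous and ordered
  expect_equal(sch$frame_start[-1], sch$frame_end[-20])
  expect_error(frame_schedule(c(0, 1), c(1, -1)), "positive")
  expect_error(frame_schedule(c(1, 0), c(1, 1)), "increasing")
  expect_error(frame_schedule(c(0, 0.5), c(1, 1)), "overlap")
})

test_that("zero input produces an identically zero TAC", {
  sch <- default_frame_schedule()
  tt <- seq(0, 110, 0.5)
  inp <- input_function(tt, rep(0, length(tt)))
  p <- twotc_params(0.1, 0.5, 2, 0.05, 0.05)
  expect_equal(simulate_2tc_tac(p, inp, sch)$conc, rep(0, 20))
  ref0 <- data.frame(time = tt, conc = 0)
  sp <- srtm_params(0.8, 0.15, 1.5)
  expect_equal(simulate_srtm_tac(sp, ref0, sch)$conc, rep(0, 20))
})

test_that("vanishing specific binding reduces the 2TCM to one-tissue kinetics", {
  sch <- default_frame_schedule()
  inp <- exp_input(step = 0.005)
  K1 <- 0.1; VND <- 0.5; vB <- 0.05
  k2 <- K1 / VND
  p <- twotc_params(K1, VND, 1e-12, 0.05, vB)
  tac <- simulate_2tc_tac(p, inp, sch)
  # independent 1TC closed form for Cp = e^{-t}:
  # C(t) = K1 (e^{-k2 t} - e^{-t}) / (1 - k2); frame-averaged analytically
  cumint <- function(t) {
    K1 * ((1 - exp(-k2 * t)) / k2 - (1 - exp(-t))) / (1 - k2)
  }
  expected <- (1 - vB) * (cumint(sch$frame_end) - cumint(sch$frame_start)) /
    sch$frame_dur +
    vB * ((exp(-sch$frame_start) - exp(-sch$frame_end)) / sch$frame_dur)
  expect_lt(max(abs(tac$conc - expected)), 1e-6)
})

test_that("2TCM frames match the closed-form biexponential convolution for an exponential input", {
  sch <- default_frame_schedule()
  inp <- exp_input(step = 0.005)
  K1 <- 0.1; VND <- 0.5; BPND <- 2; k4 <- 0.05; vB <- 0.05
  p <- twotc_params(K1, VND, BPND, k4, vB)
  tac <- simulate_2tc_tac(p, inp, sch)
  oracle <- twotc_exp_oracle(K1, VND, BPND, k4, vB)
  expect_lt(max(abs(tac$conc - oracle$frame_avg(sch))), 1e-6)
})

test_that("analytic convolution agrees with an ODE-solver solution", {
  skip_if_not_installed("deSolve")
  K1 <- 0.12; VND <- 0.4; BPND <- 3; k4 <- 0.04; vB <- 0.04
  k2 <- K1 / VND; k3 <- BPND * k4
  tt <- seq(0, 90, 0.01)
  inp <- input_function(tt, exp(-tt) + 0.3 * exp(-0.05 * tt))
  p <- twotc_params(K1, VND, BPND, k4, vB)
  rhs <- function(t, y, parms) {
    Cp <- if (t <= 0) 0 else exp(-t) + 0.3 * exp(-0.05 * t)
    list(c(K1 * Cp - (k2 + k3) * y[1] + k4 * y[2], k3 * y[1] - k4 * y[2]))
  }
  tout <- seq(0, 90, 1)
  sol <- deSolve::ode(c(0, 0), tout, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  ode_curve <- (1 - vB) * (sol[, 2] + sol[, 3]) +
    vB * (exp(-tout) + 0.3 * exp(-0.05 * tout))
  ours <- eval_2tc_curve(p, inp)
  ours <- approx(ours$time, ours$conc, xout = tout)$y
  expect_lt(max(abs(ours - ode_curve)) / max(ode_curve), 1e-5)
})

test_that("free-fraction-scaled simulation is invariant to the parameterization", {
  sch <- default_frame_schedule()
  inp <- exp_input(step = 0.05)
  p <- twotc_params(0.1, 0.5, 2, 0.05, 0.05)
  fp <- 0.07
  pf <- as_free_params(p, fp)
  tac1 <- simulate_2tc_tac(p, inp, sch)
  tac2 <- simulate_free_input_tac(pf, fp, inp, sch)
  expect_lt(max(abs(tac1$conc - tac2$conc)), 1e-10)

  # fP = 1: free parameterization coincides numerically with the standard one
  pf1 <- as_free_params(p, 1)
  tac3 <- simulate_free_input_tac(pf1, 1, inp, sch)
  expect_equal(tac3$conc, tac1$conc, tolerance = 1e-12)

  # lossless round trip
  back <- as_twotc_params(pf, fp)
  expect_equal(unlist(back), unlist(p), tolerance = 1e-12)

  expect_error(simulate_free_input_tac(pf, 0, inp, sch), "fP")
  expect_error(simulate_free_input_tac(pf, 1.2, inp, sch), "fP")
})

test_that("SRTM with R1 = 1 and zero binding returns the reference curve", {
  sch <- default_frame_schedule()
  # reference grid that already contains every frame boundary, so the
  # piecewise-linear frame averages below are exact
  tt <- sort(unique(c(seq(0, 110, 0.05), sch$frame_start, sch$frame_end)))
  ref <- data.frame(time = tt, conc = exp(-0.1 * tt) * tt)
  sp <- srtm_params(1, 0.15, 1e-12)
  tac <- simulate_srtm_tac(sp, ref, sch)
  cum <- c(0, cumsum(diff(tt) * (ref$conc[-1] + ref$conc[-length(tt)]) / 2))
  fa <- (approx(tt, cum, sch$frame_end)$y - approx(tt, cum, sch$frame_start)$y) /
    sch$frame_dur
  expect_lt(max(abs(tac$conc - fa)), 1e-6)
})

test_that("SRTM curve matches direct numeric quadrature of the convolution", {
  R1 <- 0.8; k2p <- 0.15; BPND <- 1.5
  k2 <- R1 * k2p; k2a <- k2 / (1 + BPND)
  tt <- seq(0, 110, 0.01)
  ref <- data.frame(time = tt, conc = exp(-0.1 * tt))
  sp <- srtm_params(R1, k2p, BPND)
  ours <- eval_srtm_curve(sp, ref)
  for (t0 in c(1, 5, 20, 60, 110)) {
    conv <- integrate(function(s) exp(-0.1 * s) * exp(-k2a * (t0 - s)),
                      0, t0, rel.tol = 1e-12)$value
    expected <- R1 * exp(-0.1 * t0) + (k2 - R1 * k2a) * conv
    expect_lt(abs(ours$conc[which.min(abs(tt - t0))] - expected), 1e-6)
  }
})

test_that("SRTM and 2TCM generators coincide for shared-V_ND one-tissue kinetics", {
  # reference and target both follow 1TC kinetics with the same V_ND and
  # v_B = 0; then SRTM with R1 = K1/K1_ref, k2' = K1_ref/V_ND, BP_ND = 0 is
  # exact
  sch <- default_frame_schedule()
  inp <- exp_input(step = 0.01)
  VND <- 0.5
  K1r <- 0.08; K1t <- 0.12
  eps <- 1e-12
  ref_curve <- eval_2tc_curve(twotc_params(K1r, VND, eps, 0.05, 1e-9), inp)
  tac_2tc <- simulate_2tc_tac(twotc_params(K1t, VND, eps, 0.05, 1e-9), inp, sch)
  sp <- srtm_params(K1t / K1r, K1r / VND, eps)
  tac_srtm <- simulate_srtm_tac(sp, ref_curve, sch)
  expect_lt(max(abs(tac_srtm$conc - tac_2tc$conc)) / max(tac_2tc$conc), 1e-3)
})

test_that("macro-parameter identities hold", {
  p <- twotc_params(0.1, 0.5, 2, 0.025, 0.05)
  mr <- micro_rates(p)
  expect_equal(unname(mr["k2"]), 0.2)
  expect_equal(unname(mr["k3"]), 0.05)
  m <- macro_from_micro(p)
  expect_equal(unname(m["VND"]), 0.5)
  expect_equal(unname(m["BPND"]), 2)
  expect_equal(unname(m["BPP"]), 1)
  expect_equal(unname(m["VT"]), 1.5)
  expect_equal(unname(macro_from_micro(p, fP = 0.08)["BPF"]), 12.5)
  expect_error(macro_from_micro(p, fP = 0)["BPF"], "fP")

  # V_ND = 1 makes BP_P equal BP_ND
  p1 <- twotc_params(0.1, 1, 2, 0.05, 0.05)
  m1 <- macro_from_micro(p1)
  expect_equal(unname(m1["BPP"]), unname(m1["BPND"]))

  # V_T = V_ND + BP_P for random draws (identity)
  set.seed(1)
  for (i in 1:25) {
    pp <- twotc_params(runif(1, 0.02, 0.3), runif(1, 0.1, 2),
                       runif(1, 0.01, 10), runif(1, 0.005, 0.2),
                       runif(1, 0.01, 0.2))
    mm <- macro_from_micro(pp)
    expect_equal(unname(mm["VT"]), unname(mm["VND"] + mm["BPP"]),
                 tolerance = 1e-12)
  }
})

test_that("frame averages converge to point evaluation as frames shrink", {
  # 1-second frames around t = 30 min vs the continuous curve
  p <- twotc_params(0.1, 0.5, 2, 0.05, 0.05)
  inp <- exp_input(step = 0.005, t_end = 40)
  starts <- seq(30, 30.5, by = 1 / 60)
  sch <- frame_schedule(starts, rep(1 / 60, length(starts)))
  tac <- simulate_2tc_tac(p, inp, sch)
  curve <- eval_2tc_curve(p, inp)
  at_mid <- approx(curve$time, curve$conc, xout = sch$frame_mid)$y
  expect_lt(max(abs(tac$conc - at_mid) / abs(at_mid)), 1e-4)
})

test_that("a schedule extending past the input support is an error", {
  sch <- default_frame_schedule()
  inp <- exp_input(step = 0.1, t_end = 60)
  p <- twotc_params(0.1, 0.5, 2, 0.05, 0.05)
  expect_error(simulate_2tc_tac(p, inp, sch), "cover")
  ref <- data.frame(time = seq(0, 60, 0.1), conc = 1)
  expect_error(simulate_srtm_tac(srtm_params(1, 0.1, 1), ref, sch), "cover")
})

test_that("parameter constructors reject invalid values", {
  expect_error(twotc_params(-0.1, 0.5, 2, 0.05, 0.05), "positive")
  expect_error(twotc_params(0.1, 0.5, 2, 0.05, 1.2), "vB")
  expect_error(srtm_params(0, 0.1, 1), "positive")
  expect_error(input_function(c(0, 1), c(1, -1)), "non-negative")
  expect_error(input_function(c(1, 2), c(1, 1)), "start at 0")
  expect_error(tissue_tac(1:5, default_frame_schedule()), "number of frames")
})
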