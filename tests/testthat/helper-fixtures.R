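# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# dense exponential-decay input on a fine grid (oracle-quality)
exp_input <- function(step = 0.01, t_end = 110) {
  tt <- seq(0, t_end, by = step)
  input_function(tt, exp(-tt))
}

# closed-form 2TCM solution for Cp(t) = e^{-t} (independent oracle):
# impulse response phi1 e^{-th1 t} + phi2 e^{-th2 t} convolved analytically.
twotc_exp_oracle <- function(K1, VND, BPND, k4, vB) {
  k2 <- K1 / VND
  k3 <- BPND * k4
  s <- k2 + k3 + k4
  disc <- sqrt(s^2 - 4 * k2 * k4)
  th1 <- (s + disc) / 2
  th2 <- (s - disc) / 2
  ph1 <- K1 * (th1 - k3 - k4) / (th1 - th2)
  ph2 <- K1 * (k3 + k4 - th2) / (th1 - th2)
  curve <- function(t) {
    (1 - vB) * (ph1 * (exp(-th1 * t) - exp(-t)) / (1 - th1) +
                  ph2 * (exp(-th2 * t) - exp(-t)) / (1 - th2)) +
      vB * exp(-t)
  }
  cumint <- function(t) {
    (1 - vB) * (ph1 * ((1 - exp(-th1 * t)) / th1 - (1 - exp(-t))) / (1 - th1) +
                  ph2 * ((1 - exp(-th2 * t)) / th2 - (1 - exp(-t))) / (1 - th2)) +
      vB * (1 - exp(-t))
  }
  frame_avg <- function(sch) (cumint(sch$frame_end) - cumint(sch$frame_start)) / sch$frame_dur
  list(curve = curve, cumint = cumint, frame_avg = frame_avg)
}

small_cohort <- function() {
  fixture("small_cohort", function() {
    cfg <- cohort_config(n_hv = 6, n_nrm = 6, n_ae = 0,
                         regions = c("DLPFC", "HIP", "RN"))
    generate_cohort(cfg, seed = 42)
  })
}

# moderate-scale recovery fixture shared between test files: 24 subjects,
# five regions including the raphe, the default +15% RN group effect
recovery_fixture <- function() {
  fixture("recovery", function() {
    cfg <- cohort_config(n_hv = 12, n_nrm = 12, n_ae = 0,
                         regions = c("DLPFC", "HIP", "ACC", "PCC", "RN"),
                         noise_base = 0.04)
    coh <- generate_cohort(cfg, seed = 23)
    spec <- hier_model_spec(chains = 2, warmup = 400, iter = 400)
    fit <- suppressWarnings(fit_hier(coh, spec, seed = 3))
    list(cohort = coh, fit = fit)
  })
}

small_fit <- function() {
  fixture("small_fit", function() {
    spec <- hier_model_spec(chains = 2, warmup = 250, iter = 250)
    suppressWarnings(fit_hier(small_cohort(), spec, seed = 7))
  })
}

# parameter table generated directly from the parameter-level model's own
# assumptions (trivariate SRTM log parameters), with known group effect on
# log BP_ND in the raphe nuclei.
pumba_sim_table <- function(n_per_group = 30, regions = c("DLPFC", "HIP", "RN"),
                            delta_rn = log(1.15), delta_proj = delta_rn / 2,
                            tau = c(0.1, 0.12, 0.2), rho = 0.4,
                            sigma_res = c(0.05, 0.07, 0.1), seed = 1) {
  set.seed(seed)
  groups <- rep(c("HV", "NRM"), each = n_per_group)
  n <- length(groups)
  ids <- sprintf("p%03d", seq_len(n))
  subjects <- tibble::tibble(
    subject_id = ids, group = groups,
    age = stats::runif(n, 20, 65),
    sex = sample(c("F", "M"), n, replace = TRUE)
  )
  Omega <- matrix(rho, 3, 3); diag(Omega) <- 1
  Sig <- diag(tau) %*% Omega %*% diag(tau)
  eta <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(Sig)
  bp_mean <- stats::setNames(log(c(4, 5, 2.2))[seq_along(regions)], regions)
  rows <- list()
  for (i in seq_len(n)) {
    for (r in regions) {
      eff <- if (groups[i] == "NRM") {
        if (r == "RN") delta_rn else delta_proj
      } else 0
      mu <- c(0, log(0.12), bp_mean[[r]] + eff) + eta[i, ]
      yy <- mu + stats::rnorm(3, 0, sigma_res)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = ids[i], region = r, model = "srtm", mode = "SRTM",
        parameter = c("log_R1", "log_k2prime", "log_BPND"),
        estimate = yy, se = NA_real_, converged = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  list(table = tibble::as_tibble(do.call(rbind, rows)), subjects = subjects,
       truth = list(delta_rn = delta_rn, delta_proj = delta_proj,
                    omega = Omega, tau = tau))
}
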