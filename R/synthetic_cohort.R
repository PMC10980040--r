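#' Default region table for the synthetic cohort
#'
#' Plausible population geometric means of the 2TCM parameters for a
#' serotonin-1A antagonist radioligand: high specific binding in limbic and
#' cortical projection regions, moderate binding in the raphe nuclei (RN),
#' and near-negligible binding in cerebellar grey and white matter. `noise_mult`
#' scales TAC noise per region; the raphe nuclei, a small midbrain structure,
#' is by far the noisiest.
#'
#' @return A data frame with one row per region.
#' @keywords internal
default_region_table <- function() {
  data.frame(
    region = c("DLPFC", "MPFC", "ACC", "PCC", "HIP", "AMY", "INS", "RN",
               "CBGM", "CBWM"),
    K1 = c(0.09, 0.09, 0.09, 0.095, 0.08, 0.075, 0.09, 0.06, 0.095, 0.045),
    VND = c(0.45, 0.45, 0.45, 0.45, 0.42, 0.42, 0.45, 0.38, 0.42, 0.30),
    BPND = c(3.5, 4.5, 4.0, 4.5, 5.5, 5.0, 4.5, 2.5, 0.35, 0.08),
    k4 = c(0.03, 0.03, 0.03, 0.03, 0.028, 0.028, 0.03, 0.032, 0.04, 0.05),
    vB = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.06, 0.05, 0.04),
    noise_mult = c(1, 1, 1, 1, 1.2, 1.2, 1, 3, 1.2, 2),
    is_projection = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                      FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

default_omega <- function() {
  o <- diag(5)
  rownames(o) <- colnames(o) <- param_names_2tc
  o["K1", "VND"] <- o["VND", "K1"] <- 0.5
  o["K1", "BP"] <- o["BP", "K1"] <- 0.2
  o["VND", "BP"] <- o["BP", "VND"] <- 0.45
  o["VND", "k4"] <- o["k4", "VND"] <- 0.3
  o["K1", "k4"] <- o["k4", "K1"] <- 0.15
  o["BP", "k4"] <- o["k4", "BP"] <- 0.2
  o["K1", "vB"] <- o["vB", "K1"] <- 0.1
  o
}

#' Configuration of the synthetic study cohort
#'
#' Defines the complete data-generating process for a synthetic dynamic-PET
#' study with known ground truth: three groups (healthy volunteers `HV`,
#' not-recently-medicated `NRM` and antidepressant-exposed `AE` patients,
#' default sizes 57/50/53), a multi-region set of time-activity curves
#' generated from the 2TCM with region-dependent noise (worst in the raphe
#' nuclei), correlated individual-level log-parameter deviations, group
#' effects on log BP concentrated in the raphe nuclei (projection-region
#' effects half as large on the log scale), a plasma free fraction with
#' optional group shifts and/or measurement drift over the study period, and
#' a tri-exponential arterial input template jittered per subject.
#'
#' @param n_hv,n_nrm,n_ae Group sizes.
#' @param regions Character vector of region names; must be a subset of the
#'   rows of the built-in region table.
#' @param include_cerebellum Add cerebellar grey/white matter regions.
#' @param tau_ind Between-individual SDs of the log-parameter deviations
#'   (order `K1, VND, BP, k4, vB`).
#' @param omega 5x5 correlation matrix of the individual deviations;
#'   must be symmetric positive-definite with unit diagonal.
#' @param sigma_tac TAC-level (region-within-individual) SDs of the log
#'   parameters.
#' @param delta_rn,delta_proj NRM-HV group effect on log BP in the raphe
#'   nuclei and in projection regions. Defaults `log(1.15)` and `log(1.075)`:
#'   projection effects half the raphe effect on the log scale, giving a
#'   small standardized effect size.
#' @param ae_delta_rn,ae_delta_proj AE-HV group effects (default 0).
#' @param cereb_elevation Named vector `c(NRM = , AE = )` of additive
#'   elevations of cerebellar log V_T in the patient groups (applied to
#'   log V_ND, so V_T scales by exactly `exp(elevation)`); used to probe the
#'   bias that elevated reference-region binding induces in indirect BP_ND
#'   contrasts. Default 0.
#' @param beta_age_k1,beta_age_vnd Additive change in log K1 / log V_ND per
#'   year of age.
#' @param beta_sex_k1 Additive male-female difference in log K1.
#' @param fp_meanlog,fp_sdlog Log-normal parameters of the true plasma free
#'   fraction (default geometric mean 0.07).
#' @param fp_group_shift Named additive shifts of mean log f_P per group.
#' @param drift List with `shape` in `c("none", "linear", "smooth")` and
#'   `amount`, the total fractional change in measured f_P over the study
#'   span (e.g. -0.3 for a 30% decline).
#' @param date_mode `"concurrent"` (groups interleaved uniformly over the
#'   study span) or `"staggered"` (HV imaged earlier on average, emulating
#'   sequential recruitment).
#' @param study_span_days Length of the recruitment window.
#' @param noise_base Baseline multiplicative noise level: per-frame noise SD
#'   is `noise_base * noise_mult[region] * mean(TAC) / weight`, so frames
#'   with low statistical quality (short, late, low-count) are noisiest.
#' @param aif List of arterial-input template settings: linear rise to a peak
#'   at `t_peak` minutes followed by a tri-exponential decay with amplitudes
#'   `amp` and rate constants `lambda`; per-subject log-normal jitter SDs
#'   `jitter_amp` and `jitter_tpeak`.
#' @param pf_floor,pf_tau Parent fraction model `pf(t) = floor + (1 -
#'   floor) exp(-t/tau)`; the whole-plasma curve is `parent / pf(t)`.
#' @param schedule A [frame_schedule()]; defaults to the 20-frame, 110-minute
#'   schedule.
#' @param half_life Radionuclide half-life in minutes (carbon-11).
#' @param female_frac Named per-group fraction of female subjects.
#' @param age_range Uniform age range in years.
#' @return An object of class `cohort_config` (a list).
#' @export
cohort_config <- function(n_hv = 57, n_nrm = 50, n_ae = 53,
                          regions = c("DLPFC", "MPFC", "ACC", "PCC", "HIP",
                                      "AMY", "INS", "RN"),
                          include_cerebellum = FALSE,
                          tau_ind = c(K1 = 0.10, VND = 0.15, BP = 0.20,
                                      k4 = 0.10, vB = 0.15),
                          omega = default_omega(),
                          sigma_tac = c(K1 = 0.03, VND = 0.05, BP = 0.07,
                                        k4 = 0.05, vB = 0.08),
                          delta_rn = log(1.15), delta_proj = log(1.075),
                          ae_delta_rn = 0, ae_delta_proj = 0,
                          cereb_elevation = c(NRM = 0, AE = 0),
                          beta_age_k1 = -0.002, beta_age_vnd = -0.001,
                          beta_sex_k1 = log(0.945),
                          fp_meanlog = log(0.07), fp_sdlog = 0.25,
                          fp_group_shift = c(HV = 0, NRM = 0, AE = 0),
                          drift = list(shape = "none", amount = -0.3),
                          date_mode = c("concurrent", "staggered"),
                          study_span_days = 3650,
                          noise_base = 0.05,
                          aif = list(t_peak = 1, amp = c(60, 20, 6),
                                     lambda = c(3.5, 0.35, 0.012),
                                     jitter_amp = 0.15, jitter_tpeak = 0.10),
                          pf_floor = 0.25, pf_tau = 25,
                          schedule = default_frame_schedule(),
                          half_life = 20.364,
                          female_frac = c(HV = 32 / 57, NRM = 34 / 50,
                                          AE = 30 / 53),
                          age_range = c(18, 70)) {
  date_mode <- match.arg(date_mode)
  if (include_cerebellum) regions <- union(regions, c("CBGM", "CBWM"))
  rt <- default_region_table()
  unknown <- setdiff(regions, rt$region)
  if (length(unknown)) stop("unknown regions: ", paste(unknown, collapse = ", "))
  if (any(c(n_hv, n_nrm, n_ae) < 0)) stop("group sizes must be non-negative")
  if (any(tau_ind < 0) || any(sigma_tac < 0)) stop("SDs must be non-negative")
  check_omega(omega)
  cfg <- list(
    n = c(HV = n_hv, NRM = n_nrm, AE = n_ae),
    regions = regions, region_table = rt[match(regions, rt$region), ],
    tau_ind = tau_ind, omega = omega, sigma_tac = sigma_tac,
    delta_rn = delta_rn, delta_proj = delta_proj,
    ae_delta_rn = ae_delta_rn, ae_delta_proj = ae_delta_proj,
    cereb_elevation = cereb_elevation,
    beta_age_k1 = beta_age_k1, beta_age_vnd = beta_age_vnd,
    beta_sex_k1 = beta_sex_k1,
    fp_meanlog = fp_meanlog, fp_sdlog = fp_sdlog,
    fp_group_shift = fp_group_shift, drift = drift,
    date_mode = date_mode, study_span_days = study_span_days,
    noise_base = noise_base, aif = aif, pf_floor = pf_floor, pf_tau = pf_tau,
    schedule = schedule, half_life = half_life,
    female_frac = female_frac, age_range = age_range
  )
  class(cfg) <- "cohort_config"
  cfg
}

check_omega <- function(omega) {
  if (!isSymmetric(unname(omega)) || any(abs(diag(omega) - 1) > 1e-12)) {
    stop("omega must be symmetric with unit diagonal")
  }
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("omega must be positive-definite")
  invisible(omega)
}

#' Named study-condition presets for the synthetic cohort
#'
#' `"default"`: the full-size three-group cohort under typical noise.
#' `"high_noise"`: same structure with `noise_base = 0.15`, emulating a
#' low-count acquisition in which conventional per-curve NLS quantification
#' of log BP_ND becomes unreliable (used for shrinkage-efficacy checks).
#' `"drift_confound"`: staggered scan dates plus a pure 30% linear decline
#' in measured f_P with no true group difference, the fixture for the
#' drift-confound analysis.
#' `"ref_elevated"`: includes cerebellar regions with elevated patient-group
#' cerebellar binding, the fixture for the indirect-BP_ND bias probe.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [cohort_config()].
#' @return A [cohort_config()].
#' @export
cohort_preset <- function(name = c("default", "high_noise", "drift_confound",
                                   "ref_elevated"), ...) {
  name <- match.arg(name)
  switch(name,
    default = cohort_config(...),
    high_noise = cohort_config(noise_base = 0.15, ...),
    drift_confound = cohort_config(
      date_mode = "staggered",
      drift = list(shape = "linear", amount = -0.3),
      fp_group_shift = c(HV = 0, NRM = 0, AE = 0), ...
    ),
    ref_elevated = {
      args <- list(include_cerebellum = TRUE, ...)
      if (!"cereb_elevation" %in% names(args)) {
        args$cereb_elevation <- c(NRM = 0.13, AE = 0.13)
      }
      do.call(cohort_config, args)
    }
  )
}

#' Multiplicative distortion of measured f_P over the study period
#'
#' Deterministic drift factor applied to the true plasma free fraction to
#' yield the measured value. `shape = "none"` returns 1 everywhere;
#' `"linear"` interpolates from 1 at day 0 to `1 + amount` at the end of the
#' study span; `"smooth"` adds a fixed sinusoidal ripple to the linear trend:
#' `1 + amount * d + 0.1 * sin(2 * pi * 2 * d)` with `d = date/span`.
#'
#' @param scan_date Days since study start.
#' @param config A [cohort_config()].
#' @return Multiplicative factors, same length as `scan_date`.
#' @export
fp_drift_function <- function(scan_date, config) {
  shape <- config$drift$shape
  amount <- config$drift$amount
  d <- scan_date / config$study_span_days
  switch(shape,
    none = rep(1, length(scan_date)),
    linear = 1 + amount * d,
    smooth = 1 + amount * d + 0.1 * sin(2 * pi * 2 * d),
    stop("unknown drift shape: ", shape)
  )
}

#' Assign scan dates to subjects
#'
#' In `"concurrent"` mode all groups are sampled uniformly over the study
#' span; in `"staggered"` mode HV scans are drawn from the first 60% of the
#' span and patient scans from the last 70%, emulating a study in which the
#' majority of controls were imaged before the patient groups.
#'
#' @param groups Character vector of group labels (`HV`, `NRM`, `AE`).
#' @param config A [cohort_config()].
#' @return Numeric vector of days since study start.
#' @export
assign_scan_dates <- function(groups, config) {
  span <- config$study_span_days
  n <- length(groups)
  if (config$date_mode == "concurrent") {
    return(stats::runif(n, 0, span))
  }
  out <- numeric(n)
  hv <- groups == "HV"
  out[hv] <- stats::runif(sum(hv), 0, 0.6 * span)
  out[!hv] <- stats::runif(sum(!hv), 0.3 * span, span)
  out
}

default_input_grid <- function(t_end) {
  sort(unique(c(seq(0, min(2, t_end), by = 1 / 60),
                seq(2, min(10, t_end), by = 0.05),
                seq(10, t_end, by = 0.25), t_end)))
}

# Evaluate the (jittered) tri-exponential arterial input template.
make_input <- function(config, amp, t_peak, t_end) {
  tt <- default_input_grid(t_end)
  lam <- config$aif$lambda
  peak <- sum(amp)
  cp <- ifelse(tt <= t_peak, peak * tt / t_peak,
               amp[1] * exp(-lam[1] * (tt - t_peak)) +
               amp[2] * exp(-lam[2] * (tt - t_peak)) +
               amp[3] * exp(-lam[3] * (tt - t_peak)))
  pf <- config$pf_floor + (1 - config$pf_floor) * exp(-tt / config$pf_tau)
  input_function(time = tt, parent_plasma = cp, whole_plasma = cp / pf)
}

group_bp_effect <- function(config, group, region_row) {
  if (group == "HV") return(0)
  if (region_row$region %in% c("CBGM", "CBWM")) return(0)
  if (region_row$region == "RN") {
    if (group == "NRM") config$delta_rn else config$ae_delta_rn
  } else {
    if (group == "NRM") config$delta_proj else config$ae_delta_proj
  }
}

# Patient-group elevation of cerebellar total binding, applied to log V_ND
# so that log V_T = log V_ND + log(1 + BP_ND) shifts by exactly the
# configured amount (cerebellar BP_ND is far too small for a BP elevation
# alone to move V_T appreciably).
group_vnd_effect <- function(config, group, region_row) {
  if (group == "HV") return(0)
  if (region_row$region %in% c("CBGM", "CBWM")) {
    unname(config$cereb_elevation[group])
  } else {
    0
  }
}

#' Generate a complete synthetic study dataset
#'
#' Draws demographics, scan dates, true and measured plasma free fractions,
#' subject-level arterial input functions, true kinetic parameters with the
#' configured multivariate structure (global/region means + correlated
#' individual deviations + TAC-level deviations + covariate effects), and
#' noisy frame-averaged TACs through the 2TCM simulator. Noise is additive
#' Gaussian with per-frame SD inversely proportional to the NLS weight and
#' scaled per region (largest in the raphe nuclei). Fully reproducible from
#' `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param simulate_tacs If `FALSE`, only demographics and true parameters are
#'   generated (fast path for large-sample checks of the parameter model).
#' @return A list of class `pet_cohort` with elements `subjects` (tibble),
#'   `inputs` (named list of [input_function()]), `tacs` (long tibble),
#'   `truth` (true parameters, individual deviations, generating effects,
#'   `omega`) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            simulate_tacs = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  groups <- rep(names(config$n), times = config$n)
  n <- length(groups)
  ids <- sprintf("s%03d", seq_len(n))
  sex <- unlist(lapply(names(config$n), function(g) {
    ng <- config$n[[g]]
    nf <- round(config$female_frac[[g]] * ng)
    sample(c(rep("F", nf), rep("M", ng - nf)))
  }))
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  dates <- assign_scan_dates(groups, config)
  fp_true <- exp(stats::rnorm(n, config$fp_meanlog +
                                config$fp_group_shift[groups], config$fp_sdlog))
  fp_true <- pmin(pmax(fp_true, 0.02), 0.5)
  fp_meas <- fp_true * fp_drift_function(dates, config)

  subjects <- tibble::tibble(
    subject_id = ids, group = groups, age = age, sex = sex,
    fP_true = fp_true, fP_measured = fp_meas, scan_date = dates
  )

  # individual-level correlated deviations (column scaling by tau keeps the
  # construction valid when some SDs are exactly zero)
  eta <- (matrix(stats::rnorm(n * 5), n, 5) %*% chol(config$omega)) %*%
    diag(config$tau_ind, 5)
  colnames(eta) <- param_names_2tc

  rt <- config$region_table
  nR <- nrow(rt)
  age_c <- age - 40 # centre age effects at 40 y
  sex_eff <- ifelse(sex == "M", 1, 0)

  truth_rows <- vector("list", n * nR)
  k <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(nR)) {
      k <- k + 1
      rr <- rt[j, ]
      mu <- c(
        log(rr$K1) + config$beta_age_k1 * age_c[i] +
          config$beta_sex_k1 * sex_eff[i],
        log(rr$VND) + config$beta_age_vnd * age_c[i] +
          group_vnd_effect(config, groups[i], rr),
        log(rr$BPND) + group_bp_effect(config, groups[i], rr),
        log(rr$k4),
        log(rr$vB)
      )
      th <- mu + eta[i, ] + stats::rnorm(5, 0, config$sigma_tac)
      truth_rows[[k]] <- data.frame(
        subject_id = ids[i], region = rr$region, group = groups[i],
        log_K1 = th[1], log_VND = th[2], log_BPND = th[3],
        log_k4 = th[4], log_vB = min(th[5], log(0.5)),
        stringsAsFactors = FALSE
      )
    }
  }
  truth_params <- tibble::as_tibble(do.call(rbind, truth_rows))
  truth_params$log_BPP <- truth_params$log_VND + truth_params$log_BPND
  truth_params$log_VT <- truth_params$log_VND +
    log1p(exp(truth_params$log_BPND))

  truth <- list(
    params = truth_params, eta = eta, omega = config$omega,
    tau_ind = config$tau_ind,
    effects = list(delta_rn = config$delta_rn, delta_proj = config$delta_proj,
                   ae_delta_rn = config$ae_delta_rn,
                   ae_delta_proj = config$ae_delta_proj),
    seed = seed
  )

  out <- list(subjects = subjects, inputs = NULL, tacs = NULL, truth = truth,
              config = config)
  class(out) <- "pet_cohort"
  if (!simulate_tacs) return(out)

  t_end <- max(config$schedule$frame_end)
  inputs <- vector("list", n)
  names(inputs) <- ids
  for (i in seq_len(n)) {
    amp <- config$aif$amp * exp(stats::rnorm(3, 0, config$aif$jitter_amp))
    t_peak <- config$aif$t_peak * exp(stats::rnorm(1, 0, config$aif$jitter_tpeak))
    inputs[[i]] <- make_input(config, amp, t_peak, t_end)
  }

  sch <- config$schedule
  tac_rows <- vector("list", n * nR)
  k <- 0
  for (i in seq_len(n)) {
    g <- sim_grid(inputs[[i]], sch)
    for (j in seq_len(nR)) {
      k <- k + 1
      p <- truth_params[truth_params$subject_id == ids[i] &
                          truth_params$region == rt$region[j], ]
      clean <- .tac_2tc_frames(g$time, g$cp, g$wpI, g$istart, g$iend,
                               exp(p$log_K1), exp(p$log_VND), exp(p$log_BPND),
                               exp(p$log_k4), exp(p$log_vB))
      w <- compute_weights(sch$frame_start, sch$frame_dur, clean,
                           half_life = config$half_life)
      sd_f <- config$noise_base * rt$noise_mult[j] * mean(clean) / w
      conc <- clean + stats::rnorm(length(clean), 0, sd_f)
      tac_rows[[k]] <- data.frame(
        subject_id = ids[i], region = rt$region[j],
        frame_start = sch$frame_start, frame_dur = sch$frame_dur,
        conc = conc, conc_true = clean, stringsAsFactors = FALSE
      )
    }
  }
  out$inputs <- inputs
  out$tacs <- tibble::as_tibble(do.call(rbind, tac_rows))
  out
}
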