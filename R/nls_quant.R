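#' Frame weights for weighted nonlinear least squares
#'
#' Weights are the square root of the product of the frame duration and the
#' frame value after un-correcting for radioactive decay at the frame
#' midpoint: `w_i = sqrt(dur_i * max(0, conc_i * 2^(-t_mid_i / half_life)))`,
#' then normalized to mean 1 per TAC. Negative frame values are clamped to
#' zero before weighting.
#'
#' @param frame_start,frame_dur Frame start times and durations in minutes.
#' @param conc Decay-corrected frame values.
#' @param half_life Radionuclide half-life in minutes (default carbon-11,
#'   20.364 min).
#' @param normalize Normalize weights to mean 1 (default). Point estimates
#'   from weighted NLS are invariant to this scaling.
#' @return Non-negative weight vector.
#' @examples
#' compute_weights(95, 10, 1.0) # a single late 10-min frame
#' @export
compute_weights <- function(frame_start, frame_dur, conc,
                            half_life = 20.364, normalize = TRUE) {
  if (any(frame_dur <= 0)) stop("frame durations must be positive")
  if (half_life <= 0) stop("half_life must be positive")
  t_mid <- frame_start + frame_dur / 2
  uncorr <- pmax(0, conc) * 2^(-t_mid / half_life)
  w <- sqrt(frame_dur * uncorr)
  if (all(w == 0)) stop("degenerate weights: all frame values are zero")
  if (normalize) w <- w / mean(w)
  w
}

# Fixed multi-start grid on the log scale: robustness without randomness.
nls_starts_2tc <- function(mode) {
  base <- expand.grid(
    log_K1 = log(c(0.05, 0.15)),
    log_VND = log(c(0.3, 0.8)),
    log_BP = log(c(0.5, 5))
  )
  starts <- lapply(seq_len(nrow(base)), function(i) {
    c(base$log_K1[i], base$log_VND[i], base$log_BP[i], log(0.03), log(0.05))
  })
  if (mode != "BPND") {
    # BP column stores log BP_P (or BP_F): shift the grid by log V_ND
    starts <- lapply(starts, function(s) { s[3] <- s[3] + s[2]; s })
  }
  starts
}

nls_bounds_2tc <- function() {
  list(lower = c(log(1e-3), log(0.01), log(1e-3), log(1e-4), log(1e-4)),
       upper = c(log(2), log(10), log(500), log(1), log(0.2)))
}

#' Conventional weighted NLS quantification of a 2TCM TAC
#'
#' Minimizes the weighted sum of squared differences between the observed
#' frame values and the frame-averaged 2TCM model over the five log
#' parameters of the chosen parameterization (`BPND`: log K1, log V_ND,
#' log BP_ND, log k4, log v_B; `BPP`: BP_ND replaced by BP_P = V_ND BP_ND;
#' `BPF`: input scaled by `fP`, parameters log K1/f_P, log V_ND/f_P, log
#' BP_F). Box-constrained quasi-Newton refinement is run from a fixed grid of
#' eight starting points and the best local optimum is returned.
#'
#' @param tac A [tissue_tac()].
#' @param input An [input_function()].
#' @param mode Outcome parameterization.
#' @param fP Plasma free fraction; required for `mode = "BPF"`.
#' @param weights Optional frame weights; computed from the observed TAC via
#'   [compute_weights()] if missing.
#' @param half_life Passed to [compute_weights()].
#' @return A list of class `nls_fit`: log-scale `estimate` (named), `se`
#'   (approximate, from the weighted Hessian), `rss`, `converged`, `weights`,
#'   `fitted`, and the implied micro/macro parameters.
#' @export
fit_2tc_nls <- function(tac, input, mode = c("BPND", "BPP", "BPF"), fP = NULL,
                        weights = NULL, half_life = 20.364) {
  mode <- match.arg(mode)
  stopifnot(inherits(tac, "tissue_tac"))
  sch <- tac$schedule
  if (is.null(weights)) {
    weights <- compute_weights(sch$frame_start, sch$frame_dur, tac$conc,
                               half_life = half_life)
  }
  if (mode == "BPF") {
    check_fp(fP)
    input <- input_function(input$time, input$parent_plasma * fP,
                            input$whole_plasma)
  }
  g <- sim_grid(input, sch)
  y <- tac$conc
  bp_pp <- mode != "BPND" # log BP column stores log(VND * BPND)
  obj <- function(th) {
    bpnd <- if (bp_pp) exp(th[3] - th[2]) else exp(th[3])
    mu <- .tac_2tc_frames(g$time, g$cp, g$wpI, g$istart, g$iend,
                          exp(th[1]), exp(th[2]), bpnd, exp(th[4]), exp(th[5]))
    sum((weights * (y - mu))^2)
  }
  b <- nls_bounds_2tc()
  if (bp_pp) { # bounds on log BP_P = log VND + log BPND
    b$lower[3] <- b$lower[2] + b$lower[3]
    b$upper[3] <- b$upper[2] + b$upper[3]
  }
  starts <- nls_starts_2tc(mode)
  if (mode == "BPF") {
    # parameters are K1/f_P, V_ND/f_P and BP_F: shift the start grid and the
    # box constraints accordingly
    off <- -log(fP)
    b$lower[1:3] <- b$lower[1:3] + off
    b$upper[1:3] <- b$upper[1:3] + off
    starts <- lapply(starts, function(s) { s[1:3] <- s[1:3] + off; s })
  }
  best <- NULL
  conv <- FALSE
  for (s in starts) {
    fit <- try(stats::nlminb(s, obj, lower = b$lower, upper = b$upper,
                             control = list(iter.max = 400, eval.max = 800)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$objective < best$objective) {
      best <- fit
      conv <- fit$convergence == 0
    }
  }
  if (is.null(best)) {
    return(structure(list(estimate = rep(NA_real_, 5), se = rep(NA_real_, 5),
                          rss = NA_real_, converged = FALSE,
                          weights = weights, mode = mode),
                     class = "nls_fit"))
  }
  th <- best$par
  pn <- c("log_K1", "log_VND",
          switch(mode, BPND = "log_BPND", BPP = "log_BPP", BPF = "log_BPF"),
          "log_k4", "log_vB")
  names(th) <- pn
  se <- nls_se(obj, th, best$objective, length(y))
  bpnd <- if (bp_pp) exp(th[3] - th[2]) else exp(th[3])
  mu <- .tac_2tc_frames(g$time, g$cp, g$wpI, g$istart, g$iend,
                        exp(th[1]), exp(th[2]), bpnd, exp(th[4]), exp(th[5]))
  structure(list(estimate = th, se = se, rss = best$objective,
                 converged = conv, weights = weights, fitted = mu,
                 mode = mode, log_BPND = log(bpnd)),
            class = "nls_fit")
}

# Approximate SEs from a finite-difference Hessian of the weighted SSE
# (Gaussian approximation, sigma^2 estimated from the residual SSE).
nls_se <- function(obj, th, rss, nobs) {
  p <- length(th)
  if (nobs <= p) return(rep(NA_real_, p))
  h <- 1e-4
  H <- matrix(NA_real_, p, p)
  f0 <- obj(th)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- rep(0, p); ei[i] <- h; ej[j] <- h
      H[i, j] <- H[j, i] <-
        (obj(th + ei + ej) - obj(th + ei) - obj(th + ej) + f0) / h^2
    }
  }
  s2 <- rss / (nobs - p)
  V <- try(solve(H / 2) * s2, silent = TRUE)
  if (inherits(V, "try-error")) return(rep(NA_real_, p))
  d <- diag(V)
  out <- rep(NA_real_, p)
  ok <- is.finite(d) & d > 0
  out[ok] <- sqrt(d[ok])
  out
}

nls_starts_srtm <- function() {
  base <- expand.grid(log_R1 = log(c(0.7, 1.3)),
                      log_k2p = log(c(0.05, 0.2)),
                      log_BP = log(c(0.5, 5)))
  lapply(seq_len(nrow(base)), function(i) {
    c(base$log_R1[i], base$log_k2p[i], base$log_BP[i])
  })
}

#' Weighted NLS quantification with the simplified reference tissue model
#'
#' @param tac A [tissue_tac()] for the target region.
#' @param ref Reference-region curve: a data frame with `time` and `conc`
#'   (continuous curve), or a [tissue_tac()] whose frame values are
#'   interpolated at frame midpoints (with zero at time zero).
#' @inheritParams fit_2tc_nls
#' @return A list of class `nls_fit` with log-scale estimates of `R1`,
#'   `k2prime` and `BP_ND`.
#' @export
fit_srtm_nls <- function(tac, ref, weights = NULL, half_life = 20.364) {
  stopifnot(inherits(tac, "tissue_tac"))
  sch <- tac$schedule
  if (inherits(ref, "tissue_tac")) {
    ref <- data.frame(time = c(0, ref$schedule$frame_mid),
                      conc = c(0, ref$conc))
  }
  if (is.null(weights)) {
    weights <- compute_weights(sch$frame_start, sch$frame_dur, tac$conc,
                               half_life = half_life)
  }
  bounds <- sort(unique(c(sch$frame_start, sch$frame_end)))
  tt <- sort(unique(c(ref$time, bounds)))
  tt <- tt[tt <= max(sch$frame_end) + 1e-12]
  cref <- stats::approx(ref$time, ref$conc, xout = tt, rule = 2)$y
  refI <- cumtrapz(tt, cref)
  ib <- match_boundary(tt, sch)
  y <- tac$conc
  obj <- function(th) {
    mu <- .tac_srtm_frames(tt, cref, refI, ib$istart, ib$iend,
                           exp(th[1]), exp(th[2]), exp(th[3]))
    sum((weights * (y - mu))^2)
  }
  lower <- c(log(0.05), log(1e-3), log(1e-6))
  upper <- c(log(5), log(2), log(100))
  best <- NULL
  conv <- FALSE
  for (s in nls_starts_srtm()) {
    fit <- try(stats::nlminb(s, obj, lower = lower, upper = upper,
                             control = list(iter.max = 400, eval.max = 800)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$objective < best$objective) {
      best <- fit
      conv <- fit$convergence == 0
    }
  }
  th <- best$par
  names(th) <- c("log_R1", "log_k2prime", "log_BPND")
  se <- nls_se(obj, th, best$objective, length(y))
  mu <- .tac_srtm_frames(tt, cref, refI, ib$istart, ib$iend,
                         exp(th[1]), exp(th[2]), exp(th[3]))
  structure(list(estimate = th, se = se, rss = best$objective,
                 converged = conv, weights = weights, fitted = mu,
                 mode = "SRTM"),
            class = "nls_fit")
}

#' NLS quantification of every TAC in a cohort
#'
#' Runs [fit_2tc_nls()] (or [fit_srtm_nls()] against a reference region) for
#' each subject-by-region TAC and returns a tidy parameter table, the input
#' schema for the parameter-level hierarchical model.
#'
#' @param cohort A `pet_cohort` from [generate_cohort()] (or an equivalent
#'   list with `tacs`, `inputs`, `subjects`, `config`).
#' @param model `"2tc"` or `"srtm"`.
#' @param mode Passed to [fit_2tc_nls()].
#' @param ref_region Reference region name for `model = "srtm"`.
#' @param use_true_ref Use the noiseless reference curve (when the cohort
#'   carries `conc_true`) rather than the noisy reference TAC.
#' @return A tibble: `subject_id`, `region`, `model`, `mode`, `parameter`,
#'   `estimate`, `se`, `converged`.
#' @export
fit_nls_cohort <- function(cohort, model = c("2tc", "srtm"),
                           mode = c("BPND", "BPP", "BPF"),
                           ref_region = "CBWM", use_true_ref = FALSE) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  sch <- cohort$config$schedule
  half_life <- cohort$config$half_life
  tacs <- cohort$tacs
  subs <- unique(tacs$subject_id)
  rows <- list()
  for (id in subs) {
    sub_tacs <- tacs[tacs$subject_id == id, ]
    regions <- unique(sub_tacs$region)
    if (model == "srtm") {
      rtac <- sub_tacs[sub_tacs$region == ref_region, ]
      if (nrow(rtac) == 0) stop("reference region ", ref_region, " missing for ", id)
      rconc <- if (use_true_ref && "conc_true" %in% names(rtac)) {
        rtac$conc_true
      } else {
        rtac$conc
      }
      ref <- data.frame(time = c(0, sch$frame_mid), conc = c(0, rconc))
      regions <- setdiff(regions, ref_region)
    }
    fP <- cohort$subjects$fP_measured[cohort$subjects$subject_id == id]
    for (rg in regions) {
      conc <- sub_tacs$conc[sub_tacs$region == rg]
      tac <- tissue_tac(conc, sch, subject_id = id, region = rg)
      fit <- if (model == "2tc") {
        fit_2tc_nls(tac, cohort$inputs[[id]], mode = mode,
                    fP = if (mode == "BPF") fP else NULL,
                    half_life = half_life)
      } else {
        fit_srtm_nls(tac, ref, half_life = half_life)
      }
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = id, region = rg, model = model,
        mode = if (model == "2tc") mode else "SRTM",
        parameter = names(fit$estimate),
        estimate = unname(fit$estimate), se = unname(fit$se),
        converged = fit$converged, stringsAsFactors = FALSE
      )
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}
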