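#' @useDynLib hbpet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importFrom rlang .data
NULL

param_names_2tc <- c("K1", "VND", "BP", "k4", "vB")
param_names_srtm <- c("R1", "k2prime", "BPND")

#' Frame schedule of a dynamic PET acquisition
#'
#' @param frame_start Numeric vector of frame start times (minutes).
#' @param frame_dur Numeric vector of frame durations (minutes), all `> 0`.
#'   Frames must be time-ordered and non-overlapping.
#' @return An object of class `frame_schedule`: a data frame with columns
#'   `frame_start`, `frame_dur`, `frame_mid` and `frame_end`.
#' @examples
#' sch <- default_frame_schedule()
#' sum(sch$frame_dur) # 110 minutes
#' @export
frame_schedule <- function(frame_start, frame_dur) {
  stopifnot(length(frame_start) == length(frame_dur))
  if (any(frame_dur <= 0)) stop("frame durations must be positive")
  if (is.unsorted(frame_start, strictly = TRUE)) {
    stop("frame start times must be strictly increasing")
  }
  fe <- frame_start + frame_dur
  if (any(frame_start[-1] < fe[-length(fe)] - 1e-9)) {
    stop("frames overlap")
  }
  out <- data.frame(
    frame_start = frame_start,
    frame_dur = frame_dur,
    frame_mid = frame_start + frame_dur / 2,
    frame_end = fe
  )
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Default 20-frame, 110-minute acquisition schedule
#'
#' Three 20-second frames, then 3 x 1 min, 3 x 2 min, 2 x 5 min and
#' 9 x 10 min, i.e. 20 frames spanning 110 minutes in total.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(1 / 3, 3), rep(1, 3), rep(2, 3), rep(5, 2), rep(10, 9))
  frame_schedule(frame_start = cumsum(c(0, dur[-length(dur)])), frame_dur = dur)
}

#' Arterial input function container
#'
#' Holds the metabolite-corrected parent plasma curve and the whole-plasma
#' curve (used as a proxy for whole blood in the vascular term) on a common
#' time grid. Interpolation between grid points is piecewise-linear and the
#' curves are taken as zero before time zero; no extrapolation is performed
#' beyond the last sample.
#'
#' @param time Minutes; strictly increasing, starting at 0.
#' @param parent_plasma Metabolite-corrected plasma radioactivity concentration.
#' @param whole_plasma Whole-plasma radioactivity concentration. Defaults to
#'   `parent_plasma`.
#' @return An object of class `input_function`.
#' @export
input_function <- function(time, parent_plasma, whole_plasma = parent_plasma) {
  stopifnot(length(time) == length(parent_plasma),
            length(time) == length(whole_plasma))
  if (time[1] != 0) stop("input time grid must start at 0")
  if (is.unsorted(time, strictly = TRUE)) stop("input time grid must be strictly increasing")
  if (any(parent_plasma < 0) || any(whole_plasma < 0)) {
    stop("input concentrations must be non-negative")
  }
  structure(
    list(time = as.numeric(time), parent_plasma = as.numeric(parent_plasma),
         whole_plasma = as.numeric(whole_plasma)),
    class = "input_function"
  )
}

#' Tissue time-activity curve
#'
#' @param conc Decay-corrected radioactivity concentration, one value per frame.
#' @param schedule A [frame_schedule()].
#' @param subject_id,region Identifiers.
#' @param weights Optional non-negative per-frame weights (see
#'   [compute_weights()]).
#' @return An object of class `tissue_tac`.
#' @export
tissue_tac <- function(conc, schedule, subject_id = NA_character_,
                       region = NA_character_, weights = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(conc) != nrow(schedule)) {
    stop("length(conc) must equal the number of frames")
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(conc))
    if (any(weights < 0)) stop("weights must be non-negative")
  }
  structure(
    list(subject_id = subject_id, region = region, schedule = schedule,
         conc = as.numeric(conc), weights = weights),
    class = "tissue_tac"
  )
}

#' Two-tissue compartment model parameters
#'
#' Log-scale parameter vector of the 2TCM in its `BP_ND` parameterization:
#' `K1` (mL/cm^3/min), `V_ND = K1/k2`, `BP_ND = k3/k4`, `k4` (1/min) and the
#' blood volume fraction `v_B`. All parameters are strictly positive and
#' `v_B` must lie in (0, 1).
#'
#' @param K1,VND,BPND,k4,vB Natural-scale parameter values.
#' @return An object of class `twotc_params` storing the natural logarithms.
#' @examples
#' p <- twotc_params(K1 = 0.1, VND = 0.5, BPND = 2, k4 = 0.05, vB = 0.05)
#' macro_from_micro(p)
#' @export
twotc_params <- function(K1, VND, BPND, k4, vB) {
  vals <- c(K1 = K1, VND = VND, BPND = BPND, k4 = k4, vB = vB)
  if (any(vals <= 0)) stop("all 2TCM parameters must be strictly positive")
  if (vB >= 1) stop("vB must lie in (0, 1)")
  structure(
    list(log_K1 = log(K1), log_VND = log(VND), log_BPND = log(BPND),
         log_k4 = log(k4), log_vB = log(vB)),
    class = "twotc_params"
  )
}

#' @rdname twotc_params
#' @param x A `twotc_params` object.
#' @export
micro_rates <- function(x) {
  stopifnot(inherits(x, "twotc_params"))
  K1 <- exp(x$log_K1); VND <- exp(x$log_VND)
  BPND <- exp(x$log_BPND); k4 <- exp(x$log_k4)
  c(K1 = K1, k2 = K1 / VND, k3 = BPND * k4, k4 = k4, vB = exp(x$log_vB))
}

#' Free-fraction-scaled 2TCM parameters
#'
#' Parameterization used when the input function is scaled by the measured
#' plasma free fraction `f_P`: `K1/f_P`, `V_ND/f_P`, `BP_F = BP_P/f_P`, `k4`
#' and `v_B`. Given `f_P` this converts losslessly to and from
#' [twotc_params()].
#'
#' @param K1_fP,VND_fP,BPF,k4,vB Natural-scale values of `K1/f_P`, `V_ND/f_P`,
#'   `BP_F`, `k4` and `v_B`.
#' @return An object of class `free_twotc_params`.
#' @export
free_twotc_params <- function(K1_fP, VND_fP, BPF, k4, vB) {
  vals <- c(K1_fP, VND_fP, BPF, k4, vB)
  if (any(vals <= 0)) stop("all parameters must be strictly positive")
  if (vB >= 1) stop("vB must lie in (0, 1)")
  structure(
    list(log_K1_fP = log(K1_fP), log_VND_fP = log(VND_fP), log_BPF = log(BPF),
         log_k4 = log(k4), log_vB = log(vB)),
    class = "free_twotc_params"
  )
}

#' Convert between standard and free-fraction-scaled 2TCM parameters
#'
#' @param params A [twotc_params()] or [free_twotc_params()] object.
#' @param fP Plasma free fraction in (0, 1].
#' @return The converted parameter object.
#' @export
as_free_params <- function(params, fP) {
  stopifnot(inherits(params, "twotc_params"))
  check_fp(fP)
  # BP_F = BP_P / f_P = (V_ND / f_P) * BP_ND
  free_twotc_params(
    K1_fP = exp(params$log_K1) / fP,
    VND_fP = exp(params$log_VND) / fP,
    BPF = exp(params$log_VND + params$log_BPND) / fP,
    k4 = exp(params$log_k4),
    vB = exp(params$log_vB)
  )
}

#' @rdname as_free_params
#' @export
as_twotc_params <- function(params, fP) {
  stopifnot(inherits(params, "free_twotc_params"))
  check_fp(fP)
  twotc_params(
    K1 = exp(params$log_K1_fP) * fP,
    VND = exp(params$log_VND_fP) * fP,
    BPND = exp(params$log_BPF - params$log_VND_fP),
    k4 = exp(params$log_k4),
    vB = exp(params$log_vB)
  )
}

check_fp <- function(fP) {
  if (!is.numeric(fP) || length(fP) != 1 || fP <= 0 || fP > 1) {
    stop("fP must be a single value in (0, 1]")
  }
  invisible(fP)
}

#' Simplified reference tissue model parameters
#'
#' @param R1 Relative delivery `K1/K1'` (unitless).
#' @param k2prime Reference-region efflux rate (1/min).
#' @param BPND Specific binding relative to non-displaceable uptake.
#' @return An object of class `srtm_params` storing the natural logarithms.
#' @export
srtm_params <- function(R1, k2prime, BPND) {
  if (any(c(R1, k2prime, BPND) <= 0)) stop("all SRTM parameters must be strictly positive")
  structure(
    list(log_R1 = log(R1), log_k2prime = log(k2prime), log_BPND = log(BPND)),
    class = "srtm_params"
  )
}

#' Macro-parameters from 2TCM micro-parameters
#'
#' Returns `V_ND`, `BP_ND`, `BP_P = V_ND * BP_ND`, `V_T = V_ND (1 + BP_ND)`
#' and, when `fP` is supplied, `BP_F = BP_P / f_P`.
#'
#' @param params A [twotc_params()] object.
#' @param fP Optional plasma free fraction; required for `BP_F`.
#' @return A named numeric vector.
#' @export
macro_from_micro <- function(params, fP = NULL) {
  stopifnot(inherits(params, "twotc_params"))
  VND <- exp(params$log_VND)
  BPND <- exp(params$log_BPND)
  out <- c(VND = VND, BPND = BPND, BPP = VND * BPND, VT = VND * (1 + BPND))
  if (!is.null(fP)) {
    check_fp(fP)
    out <- c(out, BPF = unname(out["BPP"]) / fP)
  }
  out
}

# Build the simulation grid: union of the input time grid and the frame
# boundaries, with the input curves linearly interpolated onto it. Errors if
# the schedule extends past the input support.
sim_grid <- function(input, schedule) {
  end_needed <- max(schedule$frame_end)
  t_in <- input$time
  if (max(t_in) < end_needed - 1e-9) {
    stop(sprintf(
      "input function covers [0, %.4g] min but the schedule requires [0, %.4g] min (uncovered: (%.4g, %.4g])",
      max(t_in), end_needed, max(t_in), end_needed
    ))
  }
  bounds <- sort(unique(c(schedule$frame_start, schedule$frame_end)))
  tt <- sort(unique(c(t_in, bounds)))
  tt <- tt[tt <= end_needed + 1e-12]
  cp <- stats::approx(t_in, input$parent_plasma, xout = tt, rule = 2)$y
  wp <- stats::approx(t_in, input$whole_plasma, xout = tt, rule = 2)$y
  ib <- match_boundary(tt, schedule)
  list(time = tt, cp = cp, wp = wp, wpI = cumtrapz(tt, wp),
       istart = ib$istart, iend = ib$iend)
}

match_boundary <- function(tt, schedule) {
  istart <- vapply(schedule$frame_start, function(b) which.min(abs(tt - b)), integer(1))
  iend <- vapply(schedule$frame_end, function(b) which.min(abs(tt - b)), integer(1))
  list(istart = istart - 1L, iend = iend - 1L) # 0-based for C++
}

cumtrapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}

#' Simulate a 2TCM tissue time-activity curve
#'
#' Solves the two-tissue compartment model by exact convolution of its
#' two-exponential impulse response with the piecewise-linear input, adds the
#' fractional blood volume contribution from the whole-plasma curve, and
#' returns frame values as time-averages over each frame (the integral over
#' the frame divided by its duration, matching how scanners bin counts).
#'
#' @param params A [twotc_params()] object.
#' @param input An [input_function()] covering the full schedule.
#' @param schedule A [frame_schedule()].
#' @inheritParams tissue_tac
#' @return A [tissue_tac()].
#' @export
simulate_2tc_tac <- function(params, input, schedule,
                             subject_id = NA_character_, region = NA_character_) {
  stopifnot(inherits(params, "twotc_params"), inherits(input, "input_function"))
  g <- sim_grid(input, schedule)
  conc <- .tac_2tc_frames(g$time, g$cp, g$wpI, g$istart, g$iend,
                          exp(params$log_K1), exp(params$log_VND),
                          exp(params$log_BPND), exp(params$log_k4),
                          exp(params$log_vB))
  tissue_tac(conc, schedule, subject_id = subject_id, region = region)
}

#' Simulate a 2TCM TAC from free-fraction-scaled parameters
#'
#' The parent-plasma input is multiplied by `fP` and the model is evaluated
#' with the `K1/f_P`, `V_ND/f_P`, `BP_F` parameterization; the resulting
#' tissue curve is identical to [simulate_2tc_tac()] with the equivalent
#' [twotc_params()].
#'
#' @param params A [free_twotc_params()] object.
#' @param fP Plasma free fraction in (0, 1].
#' @inheritParams simulate_2tc_tac
#' @return A [tissue_tac()].
#' @export
simulate_free_input_tac <- function(params, fP, input, schedule,
                                    subject_id = NA_character_,
                                    region = NA_character_) {
  stopifnot(inherits(params, "free_twotc_params"))
  check_fp(fP)
  scaled <- input_function(input$time, input$parent_plasma * fP,
                           input$whole_plasma)
  g <- sim_grid(scaled, schedule)
  # BP_ND = BP_F / (V_ND / f_P); the vascular term is unscaled whole plasma
  conc <- .tac_2tc_frames(g$time, g$cp, g$wpI, g$istart, g$iend,
                          exp(params$log_K1_fP), exp(params$log_VND_fP),
                          exp(params$log_BPF - params$log_VND_fP),
                          exp(params$log_k4), exp(params$log_vB))
  tissue_tac(conc, schedule, subject_id = subject_id, region = region)
}

#' Simulate an SRTM tissue time-activity curve
#'
#' `C_T(t) = R1 C_ref(t) + (k2 - R1 k2a) (C_ref (x) e^{-k2a t})` with
#' `k2 = R1 k2'` and `k2a = k2 / (1 + BP_ND)`, frame-averaged as in
#' [simulate_2tc_tac()]. The reference curve is treated as piecewise-linear
#' between its samples and zero before time zero.
#'
#' @param params An [srtm_params()] object.
#' @param ref A data frame with columns `time` (minutes, from 0) and `conc`
#'   giving the continuous reference-region curve, covering the schedule.
#' @inheritParams simulate_2tc_tac
#' @return A [tissue_tac()].
#' @export
simulate_srtm_tac <- function(params, ref, schedule,
                              subject_id = NA_character_,
                              region = NA_character_) {
  stopifnot(inherits(params, "srtm_params"))
  stopifnot(is.data.frame(ref), all(c("time", "conc") %in% names(ref)))
  end_needed <- max(schedule$frame_end)
  if (max(ref$time) < end_needed - 1e-9) {
    stop(sprintf(
      "reference curve covers [0, %.4g] min but the schedule requires [0, %.4g] min",
      max(ref$time), end_needed
    ))
  }
  bounds <- sort(unique(c(schedule$frame_start, schedule$frame_end)))
  tt <- sort(unique(c(ref$time, bounds)))
  tt <- tt[tt <= end_needed + 1e-12]
  cref <- stats::approx(ref$time, ref$conc, xout = tt, rule = 2)$y
  ib <- match_boundary(tt, schedule)
  conc <- .tac_srtm_frames(tt, cref, cumtrapz(tt, cref), ib$istart, ib$iend,
                           exp(params$log_R1), exp(params$log_k2prime),
                           exp(params$log_BPND))
  tissue_tac(conc, schedule, subject_id = subject_id, region = region)
}

#' Pointwise model curves (continuous evaluation)
#'
#' Evaluate the 2TCM or SRTM model curve at the input grid points rather than
#' as frame averages; used for convergence and oracle checks.
#'
#' @inheritParams simulate_2tc_tac
#' @return A data frame with columns `time` and `conc`.
#' @keywords internal
#' @export
eval_2tc_curve <- function(params, input) {
  stopifnot(inherits(params, "twotc_params"), inherits(input, "input_function"))
  conc <- .tac_2tc_curve(input$time, input$parent_plasma, input$whole_plasma,
                         exp(params$log_K1), exp(params$log_VND),
                         exp(params$log_BPND), exp(params$log_k4),
                         exp(params$log_vB))
  data.frame(time = input$time, conc = conc)
}

#' @rdname eval_2tc_curve
#' @inheritParams simulate_srtm_tac
#' @export
eval_srtm_curve <- function(params, ref) {
  stopifnot(inherits(params, "srtm_params"))
  conc <- .tac_srtm_curve(ref$time, ref$conc, exp(params$log_R1),
                          exp(params$log_k2prime), exp(params$log_BPND))
  data.frame(time = ref$time, conc = conc)
}
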