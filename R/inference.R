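#' Tail probabilities of the group-difference prior
#'
#' For a zero-centred normal prior on a log-scale group contrast,
#' `beta ~ Normal(0, sd)`, computes the prior probability assigned to
#' percent differences inside or beyond a threshold: `two_sided_within` is
#' `P(|beta| < log(1 + pct/100))`, `increase_beyond` is
#' `P(beta > log(1 + pct/100))` and `decrease_beyond` is
#' `P(beta < -log(1 + pct/100))`. With the default contrast prior SD of 0.2
#' this yields about 64% within 20%, 81% within 30%, and 9% for increases
#' beyond 30%.
#'
#' @param sd Prior SD on the log scale (> 0).
#' @param pct Percent threshold (> 0).
#' @param side One of `"two_sided_within"`, `"increase_beyond"`,
#'   `"decrease_beyond"`.
#' @return A probability.
#' @examples
#' prior_tail_probability(0.2, 20, "two_sided_within") # ~0.638
#' @export
prior_tail_probability <- function(sd, pct,
                                   side = c("two_sided_within",
                                            "increase_beyond",
                                            "decrease_beyond")) {
  side <- match.arg(side)
  if (sd <= 0) stop("sd must be positive")
  if (pct <= 0) stop("pct must be positive")
  thr <- log1p(pct / 100)
  switch(side,
    two_sided_within = stats::pnorm(thr / sd) - stats::pnorm(-thr / sd),
    increase_beyond = stats::pnorm(thr / sd, lower.tail = FALSE),
    decrease_beyond = stats::pnorm(-thr / sd)
  )
}

#' Draw group contrasts from the prior alone
#'
#' Samples the zero-centred normal prior placed on group-difference
#' contrasts of log BP; a "likelihood-off" check that the implied prior
#' mass matches [prior_tail_probability()].
#'
#' @param spec A [hier_model_spec()] (its `priors$group_sd` is used).
#' @param n Number of draws.
#' @return Numeric vector of prior contrast draws (log scale).
#' @export
sample_prior_contrast <- function(spec = hier_model_spec(), n = 10000) {
  stats::rnorm(n, 0, spec$priors$group_sd)
}

get_contrast_draws <- function(fit, name) {
  if (is.numeric(fit)) return(fit)
  dm <- draws_matrix(fit)
  if (!name %in% colnames(dm)) {
    avail <- colnames(dm)
    cand <- grep(":", avail, value = TRUE, fixed = TRUE)
    stop("unknown contrast '", name, "'; available contrasts: ",
         paste(utils::head(cand, 40), collapse = ", "))
  }
  dm[, name]
}

#' Summarize a posterior group contrast
#'
#' Transforms draws of a log-scale contrast to percent differences
#' (`100 (exp(beta) - 1)`) draw-wise, then reports the posterior median,
#' 80% and 95% quantile intervals, and the directional probabilities
#' `P(beta > 0)` and `P(beta < 0)`. Exact zeros contribute half to each
#' direction so the degenerate all-zero case gives 0.5.
#'
#' @param fit A fitted model (`pet_fit` / `pumba_fit`) or a numeric vector of
#'   contrast draws on the log scale.
#' @param name Contrast name (e.g. `"NRM-HV:RN"`); ignored when `fit` is a
#'   numeric vector.
#' @return A one-row tibble (`contrast`, `pct_diff`, interval bounds,
#'   `p_gt0`, `p_lt0`).
#' @export
summarize_contrast <- function(fit, name = NULL) {
  x <- get_contrast_draws(fit, name)
  pct <- 100 * (exp(x) - 1)
  q <- stats::quantile(pct, c(0.025, 0.1, 0.5, 0.9, 0.975), names = FALSE)
  p_gt <- mean(x > 0) + 0.5 * mean(x == 0)
  tibble::tibble(
    contrast = if (is.null(name)) NA_character_ else name,
    pct_diff = q[3],
    lo95 = q[1], lo80 = q[2], hi80 = q[4], hi95 = q[5],
    p_gt0 = p_gt, p_lt0 = 1 - p_gt
  )
}

#' Posterior probability that one contrast exceeds another
#'
#' @param fit A fitted model object.
#' @param a,b Contrast names; returns `P(a > b)` draw-wise.
#' @export
contrast_difference_probability <- function(fit, a, b) {
  da <- get_contrast_draws(fit, a)
  db <- get_contrast_draws(fit, b)
  mean(da > db) + 0.5 * mean(da == db)
}

#' Extract partially pooled individual-level estimates
#'
#' Returns, per subject, the posterior mean of the individual-level
#' (random-effect) deviation for a kinetic parameter: the mean individual
#' value after adjustment for all covariates and regional differences.
#' `parameter = "BPP"` returns individual log BP_P deviations on a common
#' scale across outcome modes: in a `BPND`-mode fit this is the sum of the
#' V_ND and BP_ND deviations; in a `BPP`-mode fit the BP deviation itself;
#' in a `BPF`-mode fit the BP_F deviation plus the subject's centred
#' log measured f_P (since BP_P = BP_F f_P).
#'
#' @param fit A `pet_fit` or `pumba_fit`.
#' @param parameter One of the model's parameter labels (`"K1"`, `"VND"`,
#'   `"BP"`, `"k4"`, `"vB"` for the TAC model; `"R1"`, `"k2prime"`, `"BPND"`
#'   for the SRTM parameter model) or `"BPP"`.
#' @return A named numeric vector, one value per subject.
#' @export
extract_individual_effects <- function(fit, parameter = "BP") {
  dm <- draws_matrix(fit)
  ids <- fit$subjects$subject_id
  pick <- function(p) {
    cols <- paste0("eta[", ids, ",", p, "]")
    missing <- setdiff(cols, colnames(dm))
    if (length(missing)) {
      stop("individual deviations for parameter '", p, "' are not in the model")
    }
    colMeans(dm[, cols, drop = FALSE])
  }
  if (parameter == "BPP" && !inherits(fit, "pumba_fit")) {
    out <- switch(fit$mode,
      BPND = pick("VND") + pick("BP"),
      BPP = pick("BP"),
      BPF = pick("BP") + (log(fit$subjects$fP_measured) -
                            mean(log(fit$subjects$fP_measured)))
    )
  } else {
    out <- pick(parameter)
  }
  stats::setNames(as.numeric(out), ids)
}

#' Compare individual-level correlation matrices
#'
#' Descriptive pairwise comparison of posterior-mean correlation matrices
#' (no hypothesis test): for each pair, the maximum element-wise absolute
#' difference and the Frobenius distance.
#'
#' @param mats Named list of correlation matrices sharing dimension and
#'   parameter order.
#' @return A tibble with one row per pair.
#' @export
compare_correlation_matrices <- function(mats) {
  stopifnot(is.list(mats), length(mats) >= 2)
  dims <- vapply(mats, function(m) ncol(m), integer(1))
  if (length(unique(dims)) != 1 || any(vapply(mats, nrow, integer(1)) != dims[1])) {
    stop("matrices must share dimension")
  }
  if (is.null(names(mats))) names(mats) <- paste0("m", seq_along(mats))
  pairs <- utils::combn(names(mats), 2)
  out <- apply(pairs, 2, function(pr) {
    dd <- mats[[pr[1]]] - mats[[pr[2]]]
    c(max_abs = max(abs(dd)), frobenius = sqrt(sum(dd^2)))
  })
  tibble::tibble(a = pairs[1, ], b = pairs[2, ],
                 max_abs_diff = out["max_abs", ],
                 frobenius = out["frobenius", ])
}

#' Two-sample t-test power and sample size
#'
#' Sample size per group for a two-sided two-sample t-test at effect size
#' `d` (Cohen's d), computed with the noncentral-t power function: the
#' smallest integer `n` per group achieving the target power.
#'
#' @param d Cohen's d (nonzero).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param n_max Search limit.
#' @return A list of class `power_result` with `n_per_group`, the achieved
#'   `power`, `d` and `alpha`.
#' @examples
#' power_sample_size(0.32)$n_per_group # about 154
#' @export
power_sample_size <- function(d, alpha = 0.05, power = 0.8, n_max = 1e7) {
  if (d == 0) stop("d must be nonzero")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)")
  }
  d <- abs(d)
  pow_fun <- function(n) {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tc, df, ncp = ncp)
  }
  if (pow_fun(n_max) < power) stop("target power unattainable within n_max")
  lo <- 2; hi <- 2
  while (pow_fun(hi) < power) hi <- min(hi * 2, n_max)
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (pow_fun(mid) >= power) hi <- mid else lo <- mid
  }
  n <- if (pow_fun(lo) >= power) lo else hi
  structure(list(n_per_group = n, power = pow_fun(n), d = d, alpha = alpha),
            class = "power_result")
}

#' Probability of superiority for a standardized effect
#'
#' The probability that a randomly selected member of the shifted group
#' exceeds a randomly selected control under normality:
#' `Phi(d / sqrt(2))`.
#'
#' @param d Cohen's d.
#' @return A probability.
#' @examples
#' probability_of_superiority(0.32) # about 0.59
#' @export
probability_of_superiority <- function(d) {
  stats::pnorm(d / sqrt(2))
}

#' Percent RMSE reduction of one estimator against another
#'
#' `100 (1 - RMSE_a / RMSE_b)` on aligned log-scale errors against the
#' truth; positive values mean estimator `a` (typically the hierarchical
#' posterior means) is more accurate than estimator `b` (typically per-TAC
#' NLS).
#'
#' @param truth,a,b Aligned numeric vectors (log scale).
#' @return Percent reduction (scalar).
#' @export
rmse_comparison <- function(truth, a, b) {
  stopifnot(length(truth) == length(a), length(truth) == length(b))
  keep <- is.finite(truth) & is.finite(a) & is.finite(b)
  rmse_a <- sqrt(mean((a[keep] - truth[keep])^2))
  rmse_b <- sqrt(mean((b[keep] - truth[keep])^2))
  if (rmse_b == 0) stop("reference estimator has zero RMSE")
  100 * (1 - rmse_a / rmse_b)
}
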