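#' Prior settings for the hierarchical models
#'
#' Group-difference contrasts on log BP carry a zero-centred normal prior
#' with SD 0.2: this assigns roughly 64% prior probability to group
#' differences smaller than 20%, 81% to differences smaller than 30%, and
#' only 9% to increases beyond 30% (see [prior_tail_probability()]).
#' Global intercepts of the log kinetic parameters carry moderately
#' informative normal priors; hierarchy SDs carry half-normal priors; the
#' individual-level covariance carries a weak inverse-Wishart prior (its
#' conjugacy is what makes the blocked Gibbs sampler practical); the
#' observation error scale carries a vague inverse-gamma prior.
#'
#' @param group_sd SD of the normal prior on group-difference contrasts of
#'   log BP (default exactly 0.2).
#' @param bp_mean,k1_int,vnd_int,k4_int,vb_int Length-2 vectors `c(mean, sd)`
#'   of the normal priors on the global/regional intercepts of log BP,
#'   log K1, log V_ND, log k4 and log v_B.
#' @param covariate_sd SD of the normal prior on age and sex coefficients.
#' @param sd_scale Scale of the half-normal priors on pooled-deviation SDs.
#' @param obs_a,obs_b Inverse-gamma shape/rate for observation variances.
#' @param iw_df,iw_scale Inverse-Wishart degrees of freedom and scale
#'   multiplier for the individual-level covariance.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(group_sd = 0.2,
                       bp_mean = c(0, 1),
                       k1_int = c(log(0.1), 0.25),
                       vnd_int = c(log(0.5), 0.5),
                       k4_int = c(log(0.05), 0.5),
                       vb_int = c(log(0.05), 0.5),
                       covariate_sd = 0.25,
                       sd_scale = 0.3,
                       obs_a = 1, obs_b = 1e-4,
                       iw_df = 7, iw_scale = 0.1) {
  stopifnot(group_sd > 0, sd_scale > 0)
  structure(list(group_sd = group_sd, bp_mean = bp_mean, k1_int = k1_int,
                 vnd_int = vnd_int, k4_int = k4_int, vb_int = vb_int,
                 covariate_sd = covariate_sd, sd_scale = sd_scale,
                 obs_a = obs_a, obs_b = obs_b, iw_df = iw_df,
                 iw_scale = iw_scale),
            class = "prior_spec")
}

#' Specification of the joint hierarchical TAC model
#'
#' Defines the outcome parameterization, covariate structure, priors and
#' sampler settings of the joint model in which every TAC of every subject
#' is fitted simultaneously through the 2TCM. The log-parameter vector of
#' TAC (i, j) is global/region mean + correlated individual deviation +
#' TAC-level deviation + covariate terms, with group-by-region effects
#' entering log BP only. Fixed effects on log BP are per-region means, sex,
#' age and group-by-region contrasts; log K1 and log V_ND carry age and sex
#' fixed effects; all five parameters carry pooled region deviations
#' (except BP, whose region means are fixed effects) and correlated
#' individual deviations.
#'
#' @param mode Outcome parameterization of the specific-binding parameter:
#'   `"BPND"`, `"BPP"` or `"BPF"` (the latter scales each subject's input by
#'   the measured plasma free fraction).
#' @param group_model `"by_region"` (one contrast per region per non-reference
#'   group) or `"region_contrast"` (fixed effects for the raphe nuclei and
#'   for the mean projection-region difference, with pooled per-region slope
#'   deviations around the projection mean).
#' @param obs_family Frame-level error family: `"gaussian"` (default;
#'   conjugate error-scale updates) or `"student_t"`.
#' @param nu Degrees of freedom for `obs_family = "student_t"`.
#' @param chains,warmup,iter MCMC settings (post-warmup draws per chain =
#'   `iter`).
#' @param nprop Metropolis proposals per TAC per sweep.
#' @param adapt_interval Sweeps between proposal-covariance refreshes during
#'   warmup.
#' @param priors A [prior_spec()].
#' @param rn_region Name of the raphe nuclei region (for the contrast model).
#' @return A list of class `hier_model_spec`.
#' @export
hier_model_spec <- function(mode = c("BPND", "BPP", "BPF"),
                            group_model = c("by_region", "region_contrast"),
                            obs_family = c("gaussian", "student_t"), nu = 4,
                            chains = 2, warmup = 400, iter = 400, nprop = 2,
                            adapt_interval = 25, priors = prior_spec(),
                            rn_region = "RN") {
  structure(list(mode = match.arg(mode), group_model = match.arg(group_model),
                 obs_family = match.arg(obs_family), nu = nu, chains = chains,
                 warmup = warmup, iter = iter, nprop = nprop,
                 adapt_interval = adapt_interval, priors = priors,
                 rn_region = rn_region),
            class = "hier_model_spec")
}

half_normal_lp <- function(sigma, scale) -sigma^2 / (2 * scale^2)

# Slice-sample (stepping out, Neal 2003) a half-normal-prior SD on the log
# scale given residuals d ~ N(0, sigma); robust without step tuning.
update_sd_mh <- function(sigma, d, scale, step = 1, floor = 1e-4) {
  n <- length(d)
  ss <- sum(d^2)
  lt <- function(ls) {
    s <- exp(ls)
    -n * ls - ss / (2 * s^2) + half_normal_lp(s, scale) + ls
  }
  x0 <- log(max(sigma, floor))
  ly <- lt(x0) + log(stats::runif(1))
  lo <- x0 - step * stats::runif(1)
  hi <- lo + step
  lo_floor <- log(floor)
  for (i in 1:30) {
    if (lo <= lo_floor || lt(lo) < ly) break
    lo <- lo - step
  }
  lo <- max(lo, lo_floor)
  for (i in 1:30) {
    if (lt(hi) < ly) break
    hi <- hi + step
  }
  for (i in 1:50) {
    x1 <- stats::runif(1, lo, hi)
    if (lt(x1) >= ly) return(exp(x1))
    if (x1 < x0) lo <- x1 else hi <- x1
  }
  sigma
}

riwish <- function(df, S) {
  # inverse-Wishart draw with scale S
  W <- stats::rWishart(1, df, solve(S))[, , 1]
  solve(W)
}

mvrnorm1 <- function(mu, Sigma) {
  L <- chol(Sigma)
  drop(mu + t(L) %*% stats::rnorm(length(mu)))
}

# -- data preparation --------------------------------------------------------

hier_prepare <- function(cohort, spec, regions = NULL) {
  tacs <- cohort$tacs
  subjects <- cohort$subjects
  if (!is.null(regions)) tacs <- tacs[tacs$region %in% regions, ]
  sch <- cohort$config$schedule
  half_life <- cohort$config$half_life
  regs <- if (!is.null(regions)) regions else
    intersect(cohort$config$regions, unique(tacs$region))
  ids <- subjects$subject_id[subjects$subject_id %in% unique(tacs$subject_id)]
  subjects <- subjects[match(ids, subjects$subject_id), ]
  n <- length(ids)
  nR <- length(regs)
  Fm <- nrow(sch)

  key <- expand.grid(region = regs, subject_id = ids,
                     stringsAsFactors = FALSE)[, c(2, 1)]
  ntac <- nrow(key)
  y <- matrix(NA_real_, ntac, Fm)
  w <- matrix(NA_real_, ntac, Fm)
  for (k in seq_len(ntac)) {
    rowsk <- tacs[tacs$subject_id == key$subject_id[k] &
                    tacs$region == key$region[k], ]
    if (nrow(rowsk) != Fm) stop("missing frames for ", key$subject_id[k], "/",
                                key$region[k])
    y[k, ] <- rowsk$conc
    # frame SD in the observation model is sigma_region * mean(TAC) / weight:
    # the per-TAC mean absorbs cross-subject differences in signal scale
    # (injected dose, input amplitude), leaving sigma_region dimensionless
    scale_k <- max(mean(abs(rowsk$conc)), 1e-8)
    w[k, ] <- compute_weights(sch$frame_start, sch$frame_dur, rowsk$conc,
                              half_life = half_life) / scale_k
  }

  # per-subject input grids (input scaled by measured f_P in BPF mode).
  # Model evaluation inside the sampler runs on a thinned grid (fine over
  # the input peak, 0.5-min spacing late): the residual quadrature error is
  # orders of magnitude below frame-level noise, at a ~3x speed gain.
  t_end <- max(sch$frame_end)
  fit_grid <- sort(unique(c(seq(0, min(2, t_end), by = 1 / 60),
                            seq(2, min(10, t_end), by = 0.1),
                            seq(10, t_end, by = 0.5), t_end)))
  sub_t <- sub_cp <- sub_wpI <- sub_is <- sub_ie <- vector("list", n)
  for (i in seq_len(n)) {
    inp <- cohort$inputs[[ids[i]]]
    if (is.null(inp)) stop("no input function for subject ", ids[i])
    if (spec$mode == "BPF") {
      fP <- subjects$fP_measured[i]
      check_fp(fP)
      inp <- input_function(inp$time, inp$parent_plasma * fP, inp$whole_plasma)
    }
    if (max(inp$time) >= t_end - 1e-9) {
      keep <- fit_grid[fit_grid <= max(inp$time) + 1e-12]
      inp <- input_function(keep,
                            stats::approx(inp$time, inp$parent_plasma,
                                          xout = keep, rule = 2)$y,
                            stats::approx(inp$time, inp$whole_plasma,
                                          xout = keep, rule = 2)$y)
    }
    g <- sim_grid(inp, sch)
    sub_t[[i]] <- g$time; sub_cp[[i]] <- g$cp; sub_wpI[[i]] <- g$wpI
    sub_is[[i]] <- g$istart; sub_ie[[i]] <- g$iend
  }

  groups_present <- intersect(c("HV", "NRM", "AE"), unique(subjects$group))
  if (length(groups_present) == 0) groups_present <- unique(subjects$group)
  ref_group <- groups_present[1]
  list(key = key, y = y, w = w, ids = ids, regs = regs, subjects = subjects,
       sub_t = sub_t, sub_cp = sub_cp, sub_wpI = sub_wpI, sub_is = sub_is,
       sub_ie = sub_ie,
       sub_idx = match(key$subject_id, ids), reg_idx = match(key$region, regs),
       groups = groups_present, ref_group = ref_group,
       sex_c = ifelse(subjects$sex == "M", 0.5, -0.5),
       age_z = as.numeric(scale(subjects$age)),
       nR = nR, n = n, ntac = ntac, Fm = Fm)
}

# Design matrices and prior vectors per kinetic parameter.
hier_design <- function(d, spec) {
  pr <- spec$priors
  ntac <- d$ntac
  si <- d$sub_idx
  sex <- d$sex_c[si]
  age <- d$age_z[si]
  nonref <- setdiff(d$groups, d$ref_group)
  grp <- d$subjects$group[si]

  # BP design
  Xr <- sapply(d$regs, function(r) as.numeric(d$key$region == r))
  cols <- colnames(Xr) <- paste0("bp_mean[", d$regs, "]")
  X3 <- cbind(Xr, `bp_sex` = sex, `bp_age` = age)
  m0 <- c(rep(pr$bp_mean[1], d$nR), 0, 0)
  s0 <- c(rep(pr$bp_mean[2], d$nR), pr$covariate_sd, pr$covariate_sd)
  contrast_names <- character(0)
  cereb <- intersect(c("CBGM", "CBWM"), d$regs)
  if (length(nonref)) {
    if (spec$group_model == "by_region") {
      for (g in nonref) {
        for (r in d$regs) {
          cn <- paste0(g, "-", d$ref_group, ":", r)
          X3 <- cbind(X3, as.numeric(grp == g & d$key$region == r))
          colnames(X3)[ncol(X3)] <- cn
          contrast_names <- c(contrast_names, cn)
        }
      }
    } else {
      proj <- setdiff(d$regs, c(spec$rn_region, cereb))
      if (!(spec$rn_region %in% d$regs) || length(proj) < 2) {
        stop("region_contrast model needs the RN region and >= 2 projection regions")
      }
      for (g in nonref) {
        cn_rn <- paste0(g, "-", d$ref_group, ":RN")
        cn_pj <- paste0(g, "-", d$ref_group, ":proj")
        X3 <- cbind(X3, as.numeric(grp == g & d$key$region == spec$rn_region),
                    as.numeric(grp == g & d$key$region %in% proj))
        colnames(X3)[ncol(X3) - 1:0] <- c(cn_rn, cn_pj)
        contrast_names <- c(contrast_names, cn_rn, cn_pj)
        for (r in cereb) {
          cn <- paste0(g, "-", d$ref_group, ":", r)
          X3 <- cbind(X3, as.numeric(grp == g & d$key$region == r))
          colnames(X3)[ncol(X3)] <- cn
          contrast_names <- c(contrast_names, cn)
        }
      }
    }
    m0 <- c(m0, rep(0, length(contrast_names)))
    s0 <- c(s0, rep(pr$group_sd, length(contrast_names)))
  }

  X1 <- cbind(K1_int = rep(1, ntac), K1_sex = sex, K1_age = age)
  X2 <- cbind(VND_int = rep(1, ntac), VND_sex = sex, VND_age = age)
  X4 <- matrix(1, ntac, 1, dimnames = list(NULL, "k4_int"))
  X5 <- matrix(1, ntac, 1, dimnames = list(NULL, "vB_int"))
  # in BPF mode the modelled parameters are K1/f_P, V_ND/f_P and BP_F, so
  # the intercept priors are re-centred by the cohort mean log measured f_P
  fp_off <- if (spec$mode == "BPF") -mean(log(d$subjects$fP_measured)) else 0
  m0_bp <- m0
  m0_bp[seq_len(d$nR)] <- m0_bp[seq_len(d$nR)] + fp_off
  list(
    X = list(X1, X2, X3, X4, X5),
    m0 = list(c(pr$k1_int[1] + fp_off, 0, 0),
              c(pr$vnd_int[1] + fp_off, 0, 0), m0_bp,
              pr$k4_int[1], pr$vb_int[1]),
    s0 = list(c(pr$k1_int[2], rep(pr$covariate_sd, 2)),
              c(pr$vnd_int[2], rep(pr$covariate_sd, 2)), s0,
              pr$k4_int[2], pr$vb_int[2]),
    contrast_names = contrast_names,
    proj = if (spec$group_model == "region_contrast")
      setdiff(d$regs, c(spec$rn_region, cereb)) else NULL,
    nonref = nonref
  )
}

# quick 2-start NLS initialization of the per-TAC log parameters
hier_init_theta <- function(d, spec, cohort) {
  ntac <- d$ntac
  th <- matrix(NA_real_, ntac, 5)
  bp_pp <- spec$mode != "BPND"
  b <- nls_bounds_2tc()
  if (bp_pp) {
    b$lower[3] <- b$lower[2] + b$lower[3]
    b$upper[3] <- b$upper[2] + b$upper[3]
  }
  starts <- list(c(log(0.08), log(0.4), log(3) + if (bp_pp) log(0.4) else 0,
                   log(0.03), log(0.05)),
                 c(log(0.12), log(0.6), log(0.8) + if (bp_pp) log(0.6) else 0,
                   log(0.05), log(0.05)))
  if (spec$mode == "BPF") {
    off <- -mean(log(d$subjects$fP_measured))
    b$lower[1:3] <- b$lower[1:3] + off
    b$upper[1:3] <- b$upper[1:3] + off
    starts <- lapply(starts, function(s) { s[1:3] <- s[1:3] + off; s })
  }
  for (k in seq_len(ntac)) {
    si <- d$sub_idx[k]
    tt <- d$sub_t[[si]]; cp <- d$sub_cp[[si]]; wpI <- d$sub_wpI[[si]]
    is <- d$sub_is[[si]]; ie <- d$sub_ie[[si]]
    y <- d$y[k, ]; wt <- d$w[k, ]
    obj <- function(p) {
      bpnd <- if (bp_pp) exp(p[3] - p[2]) else exp(p[3])
      mu <- .tac_2tc_frames(tt, cp, wpI, is, ie, exp(p[1]), exp(p[2]), bpnd,
                            exp(p[4]), exp(p[5]))
      sum((wt * (y - mu))^2)
    }
    best <- NULL
    for (s in starts) {
      f <- try(stats::nlminb(s, obj, lower = b$lower, upper = b$upper,
                             control = list(iter.max = 150)), silent = TRUE)
      if (inherits(f, "try-error")) next
      if (is.null(best) || f$objective < best$objective) best <- f
    }
    th[k, ] <- if (is.null(best)) starts[[1]] else best$par
  }
  # keep strictly inside the vB bound
  th[, 5] <- pmin(th[, 5], log(0.35))
  th
}

#' Fit the joint hierarchical multivariate model to a cohort of TACs
#'
#' All TACs from all subjects are fitted simultaneously: each TAC's five log
#' kinetic parameters receive a Gaussian prior centred on its hierarchical
#' mean (fixed effects + pooled region deviation + correlated individual
#' deviation) with TAC-level SDs, and inform the frame data through the
#' frame-averaged 2TCM likelihood with per-region error scales. Sampling is
#' blocked Metropolis-within-Gibbs: adaptive multivariate Metropolis on each
#' TAC's parameter vector (compiled likelihood), with conjugate Gibbs draws
#' for individual deviations, fixed effects, pooled region deviations, the
#' individual-level covariance (inverse-Wishart) and, under the Gaussian
#' family, the observation variances; hierarchy SDs use log-scale Metropolis
#' under half-normal priors.
#'
#' Convergence is summarized by split-R-hat and a crude effective sample
#' size on all scalar model parameters; any fixed effect with R-hat > 1.05
#' triggers a warning recorded in the result.
#'
#' @param cohort A `pet_cohort` (or equivalent list with `subjects`, `inputs`,
#'   `tacs` and `config`).
#' @param spec A [hier_model_spec()].
#' @param regions Optional subset of regions to fit.
#' @param seed Integer seed.
#' @param init_theta Optional ntac-by-5 matrix of starting log parameters
#'   (rows ordered subject-major as in the result's `tac_index`); when
#'   absent a quick per-TAC NLS initialization is used.
#' @param verbose Print progress.
#' @return An object of class `pet_fit`: `draws` (iterations x chains x
#'   parameters array), `theta_postmean` (per-TAC posterior means of the log
#'   parameters and of log BP_ND), `tac_index`, `diagnostics`, `accept_rate`,
#'   plus the model specification and data labels.
#' @export
fit_hier <- function(cohort, spec = hier_model_spec(), regions = NULL,
                     seed = 1, init_theta = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "hier_model_spec"))
  d <- hier_prepare(cohort, spec, regions)
  des <- hier_design(d, spec)
  pr <- spec$priors
  bp_pp <- as.integer(spec$mode != "BPND")

  set.seed(seed)
  th0 <- if (is.null(init_theta)) hier_init_theta(d, spec, cohort) else init_theta
  stopifnot(nrow(th0) == d$ntac, ncol(th0) == 5)

  scalar_pars <- c(unlist(lapply(des$X, colnames)),
                   paste0("tau[", param_names_2tc, "]"),
                   omega_names(),
                   as.vector(outer(d$regs, param_names_2tc[-3],
                                   function(r, p) paste0("r[", r, ",", p, "]"))),
                   paste0("sigma_tac[", param_names_2tc, "]"),
                   paste0("sigma_reg[", param_names_2tc[-3], "]"),
                   if (spec$group_model == "region_contrast" && length(des$nonref))
                     paste0("slope_sd[", des$nonref, "]"),
                   paste0("sigma_obs[", d$regs, "]"))
  eta_pars <- as.vector(outer(param_names_2tc, d$ids,
                              function(p, i) paste0("eta[", i, ",", p, "]")))
  all_pars <- c(scalar_pars, eta_pars)

  draws <- array(NA_real_, c(spec$iter, spec$chains, length(all_pars)),
                 dimnames = list(NULL, NULL, all_pars))
  theta_sum <- matrix(0, d$ntac, 6)
  acc_total <- 0

  for (ch in seq_len(spec$chains)) {
    set.seed(seed + 1000L * ch)
    st <- hier_chain(d, des, spec, th0, pr, bp_pp, draws_slot = NULL,
                     record = function(it, vec) draws[it, ch, ] <<- vec,
                     add_theta = function(mat) theta_sum <<- theta_sum + mat,
                     jitter = 0.05 * (ch - 1), verbose = verbose, chain = ch)
    acc_total <- acc_total + st$acc_rate
  }
  theta_postmean <- theta_sum / (spec$iter * spec$chains)
  colnames(theta_postmean) <- c("log_K1", "log_VND",
                                switch(spec$mode, BPND = "log_BPND",
                                       BPP = "log_BPP", BPF = "log_BPF"),
                                "log_k4", "log_vB", "log_BPND")

  diag_tbl <- fit_diagnostics(draws, scalar_pars)
  bad <- diag_tbl$parameter[!is.na(diag_tbl$rhat) & diag_tbl$rhat > 1.05 &
                              diag_tbl$parameter %in% unlist(lapply(des$X, colnames))]
  if (length(bad)) {
    warning("R-hat > 1.05 for fixed effects: ", paste(bad, collapse = ", "))
  }

  structure(list(draws = draws, theta_postmean = theta_postmean,
                 tac_index = tibble::as_tibble(d$key),
                 spec = spec, mode = spec$mode, regions = d$regs,
                 subjects = d$subjects, groups = d$groups,
                 ref_group = d$ref_group,
                 contrast_names = des$contrast_names,
                 diagnostics = diag_tbl, rhat_warnings = bad,
                 accept_rate = acc_total / spec$chains),
            class = "pet_fit")
}

omega_names <- function(pn = param_names_2tc) {
  idx <- which(upper.tri(diag(length(pn))), arr.ind = TRUE)
  paste0("Omega[", pn[idx[, 1]], ",", pn[idx[, 2]], "]")
}

# One MCMC chain; `record` stores each post-warmup draw vector and
# `add_theta` accumulates per-TAC posterior sums.
hier_chain <- function(d, des, spec, th0, pr, bp_pp, draws_slot, record,
                       add_theta, jitter, verbose, chain) {
  ntac <- d$ntac; n <- d$n; nR <- d$nR
  theta <- th0 + matrix(stats::rnorm(ntac * 5, 0, jitter), ntac, 5)
  theta[, 5] <- pmin(theta[, 5], log(0.35))

  # initial hierarchy state from the initialized thetas
  beta <- lapply(1:5, function(p) {
    X <- des$X[[p]]
    qr.coef(qr(X), theta[, p])
  })
  beta <- lapply(1:5, function(p) {
    b <- beta[[p]]; b[is.na(b)] <- 0; b
  })
  eta <- matrix(0, n, 5)
  for (p in 1:5) {
    res <- theta[, p] - des$X[[p]] %*% beta[[p]]
    eta[, p] <- tapply(res, d$sub_idx, mean)[as.character(1:n)]
  }
  eta[is.na(eta)] <- 0
  r_dev <- matrix(0, nR, 5) # region deviations; column 3 unused
  slopes <- NULL
  slope_sd <- NULL
  if (spec$group_model == "region_contrast" && length(des$nonref)) {
    slopes <- matrix(0, length(des$nonref), nR,
                     dimnames = list(des$nonref, d$regs))
    slope_sd <- stats::setNames(rep(0.05, length(des$nonref)), des$nonref)
  }
  sigma_tac <- pmax(spec$priors$sd_scale / 3, 0.02) * rep(1, 5)
  sigma_reg <- rep(0.1, 5)
  Sigma_ind <- diag(0.15^2, 5)
  sigma_obs <- stats::setNames(rep(0.1, nR), d$regs)

  base_mean <- function() {
    m <- sapply(1:5, function(p) as.numeric(des$X[[p]] %*% beta[[p]]))
    for (p in c(1, 2, 4, 5)) m[, p] <- m[, p] + r_dev[d$reg_idx, p]
    if (!is.null(slopes)) {
      grp <- d$subjects$group[d$sub_idx]
      for (g in des$nonref) {
        sel <- grp == g & d$key$region %in% des$proj
        m[sel, 3] <- m[sel, 3] + slopes[g, d$reg_idx[sel]]
      }
    }
    m
  }
  bm <- base_mean()

  # adaptive proposal state
  prop_chol <- rep(list(diag(0.08, 5)), ntac)
  log_step <- rep(0, ntac)
  asum <- matrix(0, ntac, 5)
  aouter <- array(0, c(ntac, 5, 5))
  acount <- 0
  acc_interval <- rep(0, ntac)
  acc_all <- 0
  # shift moves 1-5: single-parameter location shifts; 6: logBP+d / logVND-d
  # (the V_ND vs BP_ND trade-off ridge at fixed BP_P); 7: logK1+d / logVND+d
  # (fixed k2). The paired directions are the practically flat axes of the
  # 2TCM likelihood; without them the location mixes extremely slowly.
  shift_dirs <- list(1L, 2L, 3L, 4L, 5L, c(3L, -2L), c(1L, 2L))
  shift_step <- rep(0.05, length(shift_dirs))
  shift_acc <- rep(0, length(shift_dirs))
  reg_tacs <- split(seq_len(ntac), d$reg_idx)
  sub_tacs <- split(seq_len(ntac), d$sub_idx)
  region_dirs <- list(1L, 2L, 3L, 4L, c(3L, -2L))
  subject_dirs <- list(1L, 2L, 3L, 4L, c(3L, -2L))
  nblock <- length(region_dirs) + length(subject_dirs)
  block_step <- rep(0.1, nblock)
  block_acc <- rep(0, nblock)
  block_try <- rep(0, nblock)
  # frozen data subsets per block (avoids re-subsetting every sweep)
  blk <- function(kk) list(kk = kk, y = d$y[kk, , drop = FALSE],
                           w = d$w[kk, , drop = FALSE],
                           si = d$sub_idx[kk] - 1L, rj = d$reg_idx[kk] - 1L)
  reg_blk <- lapply(reg_tacs, blk)
  sub_blk <- lapply(sub_tacs, blk)

  niter <- spec$warmup + spec$iter
  nu_pass <- if (spec$obs_family == "student_t") spec$nu else 0
  floor_sd <- 1e-4

  for (it in seq_len(niter)) {
    # joint location-shift Metropolis moves: translate all per-TAC values of
    # one parameter together with its intercept (region means for BP). This
    # decouples the hierarchy location from the slow per-TAC random walk,
    # which matters most for weakly identified parameters on noisy data.
    ll_cur <- .hier_loglik_total(d$sub_t, d$sub_cp, d$sub_wpI, d$sub_is,
                                 d$sub_ie, d$sub_idx - 1L, d$reg_idx - 1L,
                                 d$y, d$w, theta, sigma_obs, nu_pass, bp_pp)
    for (mv in seq_along(shift_dirs)) {
      dir <- shift_dirs[[mv]]
      delta <- stats::rnorm(1, 0, shift_step[mv])
      thp <- theta
      lp_cur <- 0
      lp_prop <- 0
      ok <- TRUE
      for (pd in dir) {
        p <- abs(pd)
        dp <- sign(pd) * delta
        thp[, p] <- thp[, p] + dp
        if (p == 5 && any(thp[, 5] > log(0.4))) { ok <- FALSE; break }
        icols <- if (p == 3) seq_len(nR) else 1L
        lp_cur <- lp_cur + sum(stats::dnorm(beta[[p]][icols],
                                            des$m0[[p]][icols],
                                            des$s0[[p]][icols], log = TRUE))
        lp_prop <- lp_prop + sum(stats::dnorm(beta[[p]][icols] + dp,
                                              des$m0[[p]][icols],
                                              des$s0[[p]][icols], log = TRUE))
      }
      if (!ok) next
      llp <- .hier_loglik_total(d$sub_t, d$sub_cp, d$sub_wpI, d$sub_is,
                                d$sub_ie, d$sub_idx - 1L, d$reg_idx - 1L,
                                d$y, d$w, thp, sigma_obs, nu_pass, bp_pp)
      if (log(stats::runif(1)) < (llp + lp_prop) - (ll_cur + lp_cur)) {
        theta <- thp
        for (pd in dir) {
          p <- abs(pd)
          icols <- if (p == 3) seq_len(nR) else 1L
          beta[[p]][icols] <- beta[[p]][icols] + sign(pd) * delta
        }
        ll_cur <- llp
        shift_acc[mv] <- shift_acc[mv] + 1
      }
    }

    # conditional block shifts: translate one parameter's per-TAC values for
    # a single region (with its region mean / pooled deviation) or a single
    # subject (with its individual deviation). These cost only the block's
    # TACs to evaluate and mix the within-hierarchy locations.
    ll_block <- function(b, th) {
      .hier_loglik_total(d$sub_t, d$sub_cp, d$sub_wpI, d$sub_is, d$sub_ie,
                         b$si, b$rj, b$y, b$w, th, sigma_obs, nu_pass, bp_pp)
    }
    for (j in seq_len(nR)) {
      b <- reg_blk[[j]]
      cur <- ll_block(b, theta[b$kk, , drop = FALSE])
      for (mv in seq_along(region_dirs)) {
        dir <- region_dirs[[mv]]
        delta <- stats::rnorm(1, 0, block_step[mv])
        thp <- theta[b$kk, , drop = FALSE]
        lp0 <- 0; lp1 <- 0
        for (pd in dir) {
          p <- abs(pd); dp <- sign(pd) * delta
          thp[, p] <- thp[, p] + dp
          if (p == 3) {
            lp0 <- lp0 + stats::dnorm(beta[[3]][j], des$m0[[3]][j],
                                      des$s0[[3]][j], log = TRUE)
            lp1 <- lp1 + stats::dnorm(beta[[3]][j] + dp, des$m0[[3]][j],
                                      des$s0[[3]][j], log = TRUE)
          } else {
            sr <- pmax(sigma_reg[p], floor_sd)
            lp0 <- lp0 + stats::dnorm(r_dev[j, p], 0, sr, log = TRUE)
            lp1 <- lp1 + stats::dnorm(r_dev[j, p] + dp, 0, sr, log = TRUE)
          }
        }
        block_try[mv] <- block_try[mv] + 1
        if (any(thp[, 5] > log(0.4))) next
        l1 <- ll_block(b, thp)
        if (log(stats::runif(1)) < (l1 + lp1) - (cur + lp0)) {
          for (pd in dir) {
            p <- abs(pd); dp <- sign(pd) * delta
            theta[b$kk, p] <- theta[b$kk, p] + dp
            if (p == 3) beta[[3]][j] <- beta[[3]][j] + dp
            else r_dev[j, p] <- r_dev[j, p] + dp
          }
          cur <- l1
          block_acc[mv] <- block_acc[mv] + 1
        }
      }
    }
    Sig_chol_inv <- solve(t(chol(Sigma_ind + diag(1e-10, 5))))
    nrm <- length(region_dirs)
    for (i in seq_len(n)) {
      b <- sub_blk[[i]]
      cur <- ll_block(b, theta[b$kk, , drop = FALSE])
      for (mv in seq_along(subject_dirs)) {
        dir <- subject_dirs[[mv]]
        delta <- stats::rnorm(1, 0, block_step[nrm + mv])
        thp <- theta[b$kk, , drop = FALSE]
        e1p <- eta[i, ]
        for (pd in dir) {
          p <- abs(pd); dp <- sign(pd) * delta
          thp[, p] <- thp[, p] + dp
          e1p[p] <- e1p[p] + dp
        }
        block_try[nrm + mv] <- block_try[nrm + mv] + 1
        if (any(thp[, 5] > log(0.4))) next
        lp0 <- -0.5 * sum((Sig_chol_inv %*% eta[i, ])^2)
        lp1 <- -0.5 * sum((Sig_chol_inv %*% e1p)^2)
        l1 <- ll_block(b, thp)
        if (log(stats::runif(1)) < (l1 + lp1) - (cur + lp0)) {
          for (pd in dir) {
            p <- abs(pd)
            theta[b$kk, p] <- theta[b$kk, p] + sign(pd) * delta
          }
          eta[i, ] <- e1p
          cur <- l1
          block_acc[nrm + mv] <- block_acc[nrm + mv] + 1
        }
      }
    }
    bm <- base_mean()

    pmean <- bm + eta[d$sub_idx, ]
    up <- .hier_update_theta(d$sub_t, d$sub_cp, d$sub_wpI, d$sub_is, d$sub_ie,
                             d$sub_idx - 1L, d$reg_idx - 1L, d$y, d$w,
                             theta, pmean, pmax(sigma_tac, floor_sd),
                             sigma_obs, prop_chol, spec$nprop, nu_pass, bp_pp,
                             log(0.4))
    theta <- up$theta
    acc_interval <- acc_interval + up$accept
    acc_all <- acc_all + sum(up$accept)

    # individual deviations (conjugate MVN)
    Sinv <- solve(Sigma_ind + diag(1e-10, 5))
    Dinv <- diag(1 / pmax(sigma_tac, floor_sd)^2)
    resid_eta <- theta - bm
    for (i in seq_len(n)) {
      kk <- which(d$sub_idx == i)
      prec <- Sinv + length(kk) * Dinv
      V <- solve(prec)
      mu <- V %*% (Dinv %*% colSums(resid_eta[kk, , drop = FALSE]))
      eta[i, ] <- mvrnorm1(drop(mu), V)
    }

    # individual-level covariance (inverse-Wishart)
    Sig_scale <- diag(pr$iw_scale, 5) + crossprod(eta)
    Sigma_ind <- riwish(pr$iw_df + n, Sig_scale)

    # fixed effects (conjugate normal), pooled region deviations and SDs
    for (p in 1:5) {
      s2 <- pmax(sigma_tac[p], floor_sd)^2
      other <- eta[d$sub_idx, p]
      if (p != 3) other <- other + r_dev[d$reg_idx, p]
      if (p == 3 && !is.null(slopes)) {
        grp <- d$subjects$group[d$sub_idx]
        for (g in des$nonref) {
          sel <- grp == g & d$key$region %in% des$proj
          other[sel] <- other[sel] + slopes[g, d$reg_idx[sel]]
        }
      }
      resid <- theta[, p] - other
      X <- des$X[[p]]
      P0 <- diag(1 / des$s0[[p]]^2, ncol(X))
      prec <- crossprod(X) / s2 + P0
      V <- solve(prec)
      mu <- V %*% (crossprod(X, resid) / s2 + P0 %*% des$m0[[p]])
      beta[[p]] <- mvrnorm1(drop(mu), V)
    }

    for (p in c(1, 2, 4, 5)) {
      s2 <- pmax(sigma_tac[p], floor_sd)^2
      resid <- theta[, p] - des$X[[p]] %*% beta[[p]] - eta[d$sub_idx, p]
      sr2 <- pmax(sigma_reg[p], floor_sd)^2
      for (j in seq_len(nR)) {
        kk <- which(d$reg_idx == j)
        v <- 1 / (length(kk) / s2 + 1 / sr2)
        m <- v * sum(resid[kk]) / s2
        r_dev[j, p] <- stats::rnorm(1, m, sqrt(v))
      }
      sigma_reg[p] <- update_sd_mh(sigma_reg[p], r_dev[, p], pr$sd_scale)
    }

    if (!is.null(slopes)) {
      s2 <- pmax(sigma_tac[3], floor_sd)^2
      grp <- d$subjects$group[d$sub_idx]
      resid <- theta[, 3] - des$X[[3]] %*% beta[[3]] - eta[d$sub_idx, 3]
      for (g in des$nonref) {
        for (j in which(d$regs %in% des$proj)) {
          kk <- which(grp == g & d$reg_idx == j)
          v <- 1 / (length(kk) / s2 + 1 / pmax(slope_sd[g], floor_sd)^2)
          m <- v * sum(resid[kk]) / s2
          slopes[g, j] <- stats::rnorm(1, m, sqrt(v))
        }
        slope_sd[g] <- update_sd_mh(slope_sd[g],
                                    slopes[g, d$regs %in% des$proj],
                                    pr$sd_scale)
      }
    }

    # interweaving draws: the likelihood and the TAC-level residual are
    # invariant when a fixed effect moves together with the compensating
    # pooled deviations, so the split between them can be resampled exactly
    # from the priors alone. This breaks the slow beta <-> eta / r random
    # walk of plain alternating Gibbs.
    Sinv_iw <- solve(Sigma_ind + diag(1e-10, 5))
    etaS <- eta %*% Sinv_iw
    for (p in 1:5) {
      icols <- if (p == 3) seq_len(nR) else 1L
      # intercept(s) vs individual deviations
      a <- n * Sinv_iw[p, p] + sum(1 / des$s0[[p]][icols]^2)
      bq <- sum(etaS[, p]) -
        sum((beta[[p]][icols] - des$m0[[p]][icols]) / des$s0[[p]][icols]^2)
      delta <- stats::rnorm(1, bq / a, sqrt(1 / a))
      beta[[p]][icols] <- beta[[p]][icols] + delta
      eta[, p] <- eta[, p] - delta
      etaS <- eta %*% Sinv_iw
      # intercept vs pooled region deviations
      if (p != 3) {
        sr2 <- pmax(sigma_reg[p], floor_sd)^2
        a <- nR / sr2 + 1 / des$s0[[p]][1]^2
        bq <- sum(r_dev[, p]) / sr2 -
          (beta[[p]][1] - des$m0[[p]][1]) / des$s0[[p]][1]^2
        delta <- stats::rnorm(1, bq / a, sqrt(1 / a))
        beta[[p]][1] <- beta[[p]][1] + delta
        r_dev[, p] <- r_dev[, p] - delta
      }
      # subject-level covariates vs individual deviations
      if (p %in% 1:3) {
        cov_cols <- if (p == 3) nR + 1:2 else 2:3
        xs <- list(d$sex_c, d$age_z)
        for (ci in seq_along(cov_cols)) {
          cc <- cov_cols[ci]
          x <- xs[[ci]]
          a <- sum(x^2) * Sinv_iw[p, p] + 1 / des$s0[[p]][cc]^2
          bq <- sum(x * etaS[, p]) -
            (beta[[p]][cc] - des$m0[[p]][cc]) / des$s0[[p]][cc]^2
          delta <- stats::rnorm(1, bq / a, sqrt(1 / a))
          beta[[p]][cc] <- beta[[p]][cc] + delta
          eta[, p] <- eta[, p] - delta * x
          etaS <- eta %*% Sinv_iw
        }
      }
    }

    bm <- base_mean()
    dres <- theta - (bm + eta[d$sub_idx, ])
    for (p in 1:5) {
      sigma_tac[p] <- update_sd_mh(sigma_tac[p], dres[, p], pr$sd_scale)
    }

    # observation error scales
    if (spec$obs_family == "gaussian") {
      for (j in seq_len(nR)) {
        kk <- which(d$reg_idx == j)
        ssr <- sum(up$wssr[kk])
        nobs <- length(kk) * d$Fm
        s2 <- 1 / stats::rgamma(1, pr$obs_a + nobs / 2, pr$obs_b + ssr / 2)
        sigma_obs[j] <- max(sqrt(s2), 1e-6)
      }
    } else {
      for (j in seq_len(nR)) {
        kk <- which(d$reg_idx == j)
        z <- (d$y[kk, , drop = FALSE] - up$mu[kk, , drop = FALSE]) *
          d$w[kk, , drop = FALSE]
        lt <- function(s) {
          sum(-log(s) - 0.5 * (spec$nu + 1) * log1p((z / s)^2 / spec$nu)) +
            half_normal_lp(s, 1) + log(s)
        }
        prop <- sigma_obs[j] * exp(stats::rnorm(1, 0, 0.1))
        if (prop > 1e-6 && log(stats::runif(1)) < lt(prop) - lt(sigma_obs[j])) {
          sigma_obs[j] <- prop
        }
      }
    }

    # proposal adaptation during warmup, targeting the conditional residual
    # theta - (hierarchy mean) so the proposal matches the per-TAC
    # conditional posterior rather than the drifting marginal
    if (it <= spec$warmup) {
      asum <- asum + dres
      acount <- acount + 1
      for (p in 1:5) for (q in 1:5) {
        aouter[, p, q] <- aouter[, p, q] + dres[, p] * dres[, q]
      }
      if (it %% spec$adapt_interval == 0 && acount >= 20) {
        srate <- shift_acc / spec$adapt_interval
        shift_step <- pmin(pmax(shift_step * exp(0.6 * (srate - 0.35)),
                                1e-3), 1)
        shift_acc <- rep(0, length(shift_dirs))
        brate <- block_acc / pmax(block_try, 1)
        block_step <- pmin(pmax(block_step * exp(0.6 * (brate - 0.35)),
                                1e-3), 1)
        block_acc <- rep(0, nblock)
        block_try <- rep(0, nblock)
        rate <- acc_interval / (spec$adapt_interval * spec$nprop)
        log_step <- log_step + 0.6 * (rate - 0.3)
        log_step <- pmin(pmax(log_step, -4), 2)
        for (k in seq_len(ntac)) {
          mk <- asum[k, ] / acount
          Ck <- aouter[k, , ] / acount - tcrossprod(mk)
          Ck <- Ck * acount / max(acount - 1, 1) + diag(1e-6, 5)
          sc <- (2.38^2 / 5) * exp(2 * log_step[k])
          L <- try(t(chol(sc * Ck)), silent = TRUE)
          if (!inherits(L, "try-error")) prop_chol[[k]] <- L
        }
        acc_interval <- rep(0, ntac)
      }
    } else {
      itr <- it - spec$warmup
      vec <- c(unlist(beta),
               sqrt(diag(Sigma_ind)),
               stats::cov2cor(Sigma_ind)[upper.tri(Sigma_ind)],
               as.vector(r_dev[, c(1, 2, 4, 5)]),
               sigma_tac, sigma_reg[c(1, 2, 4, 5)],
               if (!is.null(slopes)) slope_sd,
               sigma_obs,
               as.vector(t(eta)))
      record(itr, vec)
      log_bpnd <- if (bp_pp) theta[, 3] - theta[, 2] else theta[, 3]
      add_theta(cbind(theta, log_bpnd))
    }
    if (verbose && it %% 100 == 0) {
      message("chain ", chain, " iter ", it, "/", niter)
    }
  }
  list(acc_rate = acc_all / (niter * ntac * spec$nprop))
}

# -- convergence diagnostics -------------------------------------------------

split_rhat <- function(x) {
  # x: iterations x chains
  niter <- nrow(x)
  half <- floor(niter / 2)
  if (half < 4) return(NA_real_)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(niter - half + 1):niter, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  mu <- colMeans(sp)
  s2 <- apply(sp, 2, stats::var)
  W <- mean(s2)
  B <- nn * stats::var(mu)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_basic <- function(x) {
  # x: iterations x chains; initial-positive-sequence estimator per chain
  total <- 0
  for (ch in seq_len(ncol(x))) {
    v <- x[, ch]
    nn <- length(v)
    if (stats::sd(v) == 0) { total <- total + nn; next }
    ac <- stats::acf(v, lag.max = min(nn - 1, 100), plot = FALSE)$acf[-1]
    s <- 0
    for (l in seq_along(ac)) {
      if (ac[l] < 0.05) break
      s <- s + ac[l]
    }
    total <- total + nn / (1 + 2 * s)
  }
  total
}

fit_diagnostics <- function(draws, pars) {
  out <- lapply(pars, function(p) {
    x <- draws[, , p, drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = 1)
    c(rhat = split_rhat(x), ess = ess_basic(x))
  })
  tibble::tibble(parameter = pars,
                 rhat = vapply(out, `[[`, numeric(1), "rhat"),
                 ess = vapply(out, `[[`, numeric(1), "ess"))
}

#' Fit the RN-versus-projection region-contrast model
#'
#' Convenience wrapper for [fit_hier()] with `group_model =
#' "region_contrast"`: fixed effects for the overall group difference in the
#' raphe nuclei and for the mean difference across serotonin projection
#' regions, with pooled per-region slope deviations around the projection
#' mean. The posterior probability that the raphe effect exceeds the
#' projection-mean effect is available via
#' [contrast_difference_probability()].
#'
#' @inheritParams fit_hier
#' @export
fit_region_contrast_model <- function(cohort, spec = hier_model_spec(),
                                      regions = NULL, seed = 1,
                                      init_theta = NULL, verbose = FALSE) {
  spec$group_model <- "region_contrast"
  fit_hier(cohort, spec, regions = regions, seed = seed,
           init_theta = init_theta, verbose = verbose)
}

#' Fit the hierarchical model to a single subgroup
#'
#' Restricts the data to one group and drops all group fixed effects; used
#' to compare the individual-level correlation matrices estimated
#' independently within each subgroup.
#'
#' @param group Group label to keep.
#' @inheritParams fit_hier
#' @export
fit_subgroup <- function(cohort, group, spec = hier_model_spec(),
                         regions = NULL, seed = 1, verbose = FALSE) {
  keep <- cohort$subjects$group == group
  if (sum(keep) < 3) stop("subgroup must contain at least 3 subjects")
  sub <- cohort
  sub$subjects <- cohort$subjects[keep, ]
  sub$tacs <- cohort$tacs[cohort$tacs$subject_id %in% sub$subjects$subject_id, ]
  sub$inputs <- cohort$inputs[sub$subjects$subject_id]
  fit_hier(sub, spec, regions = regions, seed = seed, verbose = verbose)
}

#' Posterior-mean individual-level correlation matrix
#'
#' @param fit A `pet_fit` (or `pumba_fit`).
#' @return The posterior mean of the correlation matrix of the
#'   individual-level deviations.
#' @export
omega_mean <- function(fit) {
  dm <- draws_matrix(fit)
  pn <- if (inherits(fit, "pumba_fit")) param_names_srtm else param_names_2tc
  p <- length(pn)
  om <- diag(1, p)
  dimnames(om) <- list(pn, pn)
  nm <- omega_names(pn)
  idx <- which(upper.tri(om), arr.ind = TRUE)
  for (k in seq_along(nm)) {
    om[idx[k, 1], idx[k, 2]] <- om[idx[k, 2], idx[k, 1]] <- mean(dm[, nm[k]])
  }
  om
}

#' Flatten posterior draws into an iterations-by-parameters matrix
#'
#' @param fit A fitted model object with a `draws` array.
#' @return Matrix with one column per parameter, chains stacked.
#' @export
draws_matrix <- function(fit) {
  arr <- fit$draws
  dd <- dim(arr)
  out <- matrix(aperm(arr, c(1, 2, 3)), dd[1] * dd[2], dd[3])
  colnames(out) <- dimnames(arr)[[3]]
  out
}
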