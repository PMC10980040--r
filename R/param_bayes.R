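#' Specification for the parameter-level hierarchical model
#'
#' @inheritParams hier_model_spec
#' @param residual_correlated Model the TAC-level residual of the three SRTM
#'   log parameters as a correlated trivariate normal (default) rather than
#'   independent per parameter.
#' @param iter,warmup,chains Gibbs sampler settings.
#' @return A list of class `pumba_spec`.
#' @export
pumba_spec <- function(group_model = c("by_region", "region_contrast"),
                       residual_correlated = TRUE, chains = 2, warmup = 300,
                       iter = 700, priors = prior_spec(), rn_region = "RN") {
  structure(list(group_model = match.arg(group_model),
                 residual_correlated = residual_correlated, chains = chains,
                 warmup = warmup, iter = iter, priors = priors,
                 rn_region = rn_region),
            class = "pumba_spec")
}

#' Multivariate hierarchical analysis of NLS-estimated SRTM parameters
#'
#' The parameter-level counterpart of the joint TAC model: the trivariate
#' response (log R1, log k2', log BP_ND) estimated per TAC by weighted NLS
#' is modelled with the same fixed-effect structure as the joint model
#' (per-region means, sex, age and group-by-region contrasts on log BP_ND;
#' age and sex on log k2'), correlated individual-level deviations across
#' the three parameters, pooled region deviations for R1 and k2', and a
#' (by default correlated) trivariate residual. All conditional draws are
#' conjugate, so the sampler is plain Gibbs. Non-converged NLS rows are
#' excluded and counted.
#'
#' @param param_table Long parameter table as returned by
#'   [fit_nls_cohort()] (`model = "srtm"`): columns `subject_id`, `region`,
#'   `parameter` (`log_R1`, `log_k2prime`, `log_BPND`), `estimate`,
#'   `converged`.
#' @param subjects Subject covariate table (`subject_id`, `group`, `age`,
#'   `sex`).
#' @param spec A [pumba_spec()].
#' @param seed Integer seed.
#' @return An object of class `pumba_fit` (and `pet_fit`-compatible):
#'   `draws`, `diagnostics`, `contrast_names`, `n_excluded`.
#' @export
fit_pumba <- function(param_table, subjects, spec = pumba_spec(), seed = 1) {
  stopifnot(inherits(spec, "pumba_spec"))
  pr <- spec$priors
  pt <- param_table[param_table$parameter %in%
                      c("log_R1", "log_k2prime", "log_BPND"), ]
  bad_ids <- unique(pt[!pt$converged, c("subject_id", "region")])
  n_excluded <- nrow(bad_ids)
  if (n_excluded) {
    pt <- pt[!paste(pt$subject_id, pt$region) %in%
               paste(bad_ids$subject_id, bad_ids$region), ]
  }
  wide <- tidyr::pivot_wider(pt[, c("subject_id", "region", "parameter",
                                    "estimate")],
                             names_from = "parameter", values_from = "estimate")
  wide <- wide[stats::complete.cases(wide), ]
  if (!all(is.finite(as.matrix(wide[, c("log_R1", "log_k2prime", "log_BPND")])))) {
    stop("non-finite parameter estimates")
  }
  ids <- intersect(subjects$subject_id, unique(wide$subject_id))
  subjects <- subjects[match(ids, subjects$subject_id), ]
  wide <- wide[wide$subject_id %in% ids, ]
  regs <- unique(wide$region)
  n <- length(ids); nR <- length(regs); ntac <- nrow(wide)
  if (nR < 2) stop("need at least 2 regions")
  if (n < 4) stop("need at least 4 subjects")
  Y <- as.matrix(wide[, c("log_R1", "log_k2prime", "log_BPND")])
  si <- match(wide$subject_id, ids)
  rj <- match(wide$region, regs)
  sex <- ifelse(subjects$sex == "M", 0.5, -0.5)[si]
  age <- as.numeric(scale(subjects$age))[si]
  glev <- intersect(c("HV", "NRM", "AE"), unique(subjects$group))
  if (length(glev) == 0) glev <- unique(subjects$group)
  ref <- glev[1]
  nonref <- setdiff(glev, ref)
  grp <- subjects$group[si]

  # component designs: 1 = log R1, 2 = log k2prime, 3 = log BP_ND
  X1 <- cbind(R1_int = rep(1, ntac))
  X2 <- cbind(k2p_int = rep(1, ntac), k2p_sex = sex, k2p_age = age)
  Xr <- sapply(regs, function(r) as.numeric(wide$region == r))
  colnames(Xr) <- paste0("bp_mean[", regs, "]")
  X3 <- cbind(Xr, bp_sex = sex, bp_age = age)
  m3 <- c(rep(pr$bp_mean[1], nR), 0, 0)
  s3 <- c(rep(pr$bp_mean[2], nR), pr$covariate_sd, pr$covariate_sd)
  contrast_names <- character(0)
  proj <- NULL
  if (length(nonref)) {
    if (spec$group_model == "by_region") {
      for (g in nonref) for (r in regs) {
        cn <- paste0(g, "-", ref, ":", r)
        X3 <- cbind(X3, as.numeric(grp == g & wide$region == r))
        colnames(X3)[ncol(X3)] <- cn
        contrast_names <- c(contrast_names, cn)
      }
    } else {
      proj <- setdiff(regs, spec$rn_region)
      for (g in nonref) {
        cn <- paste0(g, "-", ref, c(":RN", ":proj"))
        X3 <- cbind(X3, as.numeric(grp == g & wide$region == spec$rn_region),
                    as.numeric(grp == g & wide$region %in% proj))
        colnames(X3)[ncol(X3) - 1:0] <- cn
        contrast_names <- c(contrast_names, cn)
      }
    }
    m3 <- c(m3, rep(0, length(contrast_names)))
    s3 <- c(s3, rep(pr$group_sd, length(contrast_names)))
  }
  Xc <- list(X1, X2, X3)
  m0 <- c(0, c(log(0.1), 0, 0), m3)
  s0 <- c(0.5, c(0.5, pr$covariate_sd, pr$covariate_sd), s3)
  qs <- vapply(Xc, ncol, integer(1))
  q <- sum(qs)
  off <- cumsum(c(0, qs))
  Xfull <- lapply(1:3, function(cc) {
    M <- matrix(0, ntac, q)
    M[, (off[cc] + 1):off[cc + 1]] <- Xc[[cc]]
    M
  })
  par_names <- unlist(lapply(Xc, colnames))

  cn_rank <- qr(cbind(Xc[[3]]))$rank
  if (cn_rank < ncol(Xc[[3]])) {
    cmat <- Xc[[3]]
    drop_candidates <- colnames(cmat)[qr(cmat)$pivot[-seq_len(cn_rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(drop_candidates, collapse = ", "))
  }

  scalar_pars <- c(par_names,
                   paste0("tau[", param_names_srtm, "]"),
                   omega_names(param_names_srtm),
                   paste0("sigma_res[", param_names_srtm, "]"),
                   paste0("sigma_reg[", c("R1", "k2prime"), "]"))
  eta_pars <- as.vector(outer(param_names_srtm, ids,
                              function(p, i) paste0("eta[", i, ",", p, "]")))
  all_pars <- c(scalar_pars, eta_pars)
  draws <- array(NA_real_, c(spec$iter, spec$chains, length(all_pars)),
                 dimnames = list(NULL, NULL, all_pars))

  P0 <- diag(1 / s0^2, q)

  for (ch in seq_len(spec$chains)) {
    set.seed(seed + 1000L * ch)
    beta <- stats::rnorm(q, m0, 0.05)
    eta <- matrix(0, n, 3)
    r_dev <- matrix(0, nR, 2)
    sigma_reg <- c(0.1, 0.1)
    Sigma_ind <- diag(0.1^2, 3)
    Sigma_res <- diag(0.1^2, 3)

    mean_mat <- function() {
      m <- sapply(1:3, function(cc) as.numeric(Xc[[cc]] %*%
                                                 beta[(off[cc] + 1):off[cc + 1]]))
      m[, 1] <- m[, 1] + r_dev[rj, 1]
      m[, 2] <- m[, 2] + r_dev[rj, 2]
      m
    }

    for (it in seq_len(spec$warmup + spec$iter)) {
      bmm <- mean_mat()
      Sres_inv <- solve(Sigma_res + diag(1e-10, 3))

      # individual deviations
      Sind_inv <- solve(Sigma_ind + diag(1e-10, 3))
      resid <- Y - bmm
      for (i in seq_len(n)) {
        kk <- which(si == i)
        prec <- Sind_inv + length(kk) * Sres_inv
        V <- solve(prec)
        mu <- V %*% (Sres_inv %*% colSums(resid[kk, , drop = FALSE]))
        eta[i, ] <- mvrnorm1(drop(mu), V)
      }
      Sigma_ind <- riwish(pr$iw_df + n, diag(pr$iw_scale, 3) + crossprod(eta))

      # fixed effects: joint GLS-conjugate update across the 3 components
      Z <- Y - eta[si, ]
      Z[, 1] <- Z[, 1] - r_dev[rj, 1]
      Z[, 2] <- Z[, 2] - r_dev[rj, 2]
      A <- P0
      b <- P0 %*% m0
      for (cc in 1:3) for (dd in 1:3) {
        A <- A + Sres_inv[cc, dd] * crossprod(Xfull[[cc]], Xfull[[dd]])
        b <- b + Sres_inv[cc, dd] * crossprod(Xfull[[cc]], Z[, dd])
      }
      V <- solve(A)
      V <- (V + t(V)) / 2
      beta <- mvrnorm1(drop(V %*% b), V)

      # pooled region deviations for R1 and k2prime (correlated residual)
      E <- Y - eta[si, ] - sapply(1:3, function(cc)
        as.numeric(Xc[[cc]] %*% beta[(off[cc] + 1):off[cc + 1]]))
      for (j in seq_len(nR)) {
        kk <- which(rj == j)
        prec12 <- length(kk) * Sres_inv[1:2, 1:2] + diag(1 / sigma_reg^2)
        Vj <- solve(prec12)
        mj <- Vj %*% (Sres_inv[1:2, ] %*% colSums(E[kk, , drop = FALSE]))
        r_dev[j, ] <- mvrnorm1(drop(mj), Vj)
      }
      for (p in 1:2) {
        sigma_reg[p] <- update_sd_mh(sigma_reg[p], r_dev[, p], pr$sd_scale)
      }

      # interweaving: resample the fixed-effect vs pooled-deviation split
      # along likelihood-invariant directions (see the TAC model sampler)
      Sind_inv <- solve(Sigma_ind + diag(1e-10, 3))
      etaS <- eta %*% Sind_inv
      for (cc in 1:3) {
        icols <- off[cc] + if (cc == 3) seq_len(nR) else 1L
        a <- n * Sind_inv[cc, cc] + sum(1 / s0[icols]^2)
        bq <- sum(etaS[, cc]) - sum((beta[icols] - m0[icols]) / s0[icols]^2)
        delta <- stats::rnorm(1, bq / a, sqrt(1 / a))
        beta[icols] <- beta[icols] + delta
        eta[, cc] <- eta[, cc] - delta
        etaS <- eta %*% Sind_inv
        if (cc %in% 1:2) {
          ic <- off[cc] + 1L
          a <- nR / sigma_reg[cc]^2 + 1 / s0[ic]^2
          bq <- sum(r_dev[, cc]) / sigma_reg[cc]^2 -
            (beta[ic] - m0[ic]) / s0[ic]^2
          delta <- stats::rnorm(1, bq / a, sqrt(1 / a))
          beta[ic] <- beta[ic] + delta
          r_dev[, cc] <- r_dev[, cc] - delta
        }
        cov_cols <- if (cc == 2) off[2] + 2:3 else if (cc == 3) off[3] + nR + 1:2
        if (!is.null(cov_cols)) {
          xs <- list(ifelse(subjects$sex == "M", 0.5, -0.5),
                     as.numeric(scale(subjects$age)))
          for (ci in seq_along(cov_cols)) {
            colx <- cov_cols[ci]
            x <- xs[[ci]]
            a <- sum(x^2) * Sind_inv[cc, cc] + 1 / s0[colx]^2
            bq <- sum(x * etaS[, cc]) - (beta[colx] - m0[colx]) / s0[colx]^2
            delta <- stats::rnorm(1, bq / a, sqrt(1 / a))
            beta[colx] <- beta[colx] + delta
            eta[, cc] <- eta[, cc] - delta * x
            etaS <- eta %*% Sind_inv
          }
        }
      }

      # residual covariance
      bmm <- mean_mat()
      R <- Y - bmm - eta[si, ]
      if (spec$residual_correlated) {
        Sigma_res <- riwish(pr$iw_df + ntac, diag(pr$iw_scale / 2, 3) + crossprod(R))
      } else {
        for (p in 1:3) {
          ss <- sum(R[, p]^2)
          Sigma_res[p, p] <- 1 / stats::rgamma(1, pr$obs_a + ntac / 2,
                                               pr$obs_b + ss / 2)
        }
        Sigma_res[upper.tri(Sigma_res)] <- 0
        Sigma_res[lower.tri(Sigma_res)] <- 0
      }

      if (it > spec$warmup) {
        itr <- it - spec$warmup
        draws[itr, ch, ] <- c(beta,
                              sqrt(diag(Sigma_ind)),
                              stats::cov2cor(Sigma_ind)[upper.tri(Sigma_ind)],
                              sqrt(diag(Sigma_res)),
                              sigma_reg,
                              as.vector(t(eta)))
      }
    }
  }

  diag_tbl <- fit_diagnostics(draws, scalar_pars)
  structure(list(draws = draws, spec = spec, regions = regs,
                 subjects = subjects, groups = glev, ref_group = ref,
                 contrast_names = contrast_names, diagnostics = diag_tbl,
                 n_excluded = n_excluded, mode = "SRTM"),
            class = c("pumba_fit", "pet_fit"))
}

#' True SRTM-scale parameters implied by a synthetic cohort
#'
#' Converts the 2TCM ground truth of a generated cohort into the
#' indirect-quantification scale: per subject and target region,
#' `R1 = K1 / K1_ref`, `k2' = K1_ref / V_ND_ref` and the indirect
#' `BP_ND = V_T / V_T_ref - 1` using the chosen reference region. The
#' direct (true) `log BP_ND` is carried along for bias comparisons.
#'
#' @param cohort A `pet_cohort`.
#' @param ref_region Reference region (default cerebellar white matter).
#' @return A tibble with one row per subject-by-target-region.
#' @export
srtm_truth_table <- function(cohort, ref_region = "CBWM") {
  tp <- cohort$truth$params
  if (!ref_region %in% tp$region) stop("reference region ", ref_region,
                                       " not in cohort")
  refp <- tp[tp$region == ref_region, ]
  tgt <- tp[tp$region != ref_region, ]
  m <- match(tgt$subject_id, refp$subject_id)
  tibble::tibble(
    subject_id = tgt$subject_id, region = tgt$region, group = tgt$group,
    log_R1 = tgt$log_K1 - refp$log_K1[m],
    log_k2prime = refp$log_K1[m] - refp$log_VND[m],
    log_BPND_indirect = log(exp(tgt$log_VT - refp$log_VT[m]) - 1),
    log_BPND_direct = tgt$log_BPND
  )
}

#' Bias in indirect BP_ND group contrasts under reference-region elevation
#'
#' When the reference region carries specific binding that is elevated in
#' patient groups, indirect `BP_ND = V_T / V_ref - 1` contrasts are biased
#' downward relative to the direct truth. This probe generates cohorts with
#' the requested patient-group elevations of cerebellar log BP, computes for
#' each the group contrast (difference of group means of log BP_ND) on the
#' indirect scale and on the direct scale in every target region, and
#' returns the induced shift.
#'
#' @param elevations Numeric vector of additive log V_T elevations of the
#'   patient cerebellar regions (0 = no-bias null).
#' @param config Base [cohort_config()]; cerebellar regions are added
#'   automatically.
#' @param groups Which patient group to contrast against HV.
#' @param ref_region Reference region.
#' @param seed Integer seed (one cohort per elevation, common seed).
#' @return A tibble: `elevation`, `region`, `direct_contrast`,
#'   `indirect_contrast`, `shift` (indirect minus direct, log units).
#' @export
indirect_bpnd_bias_probe <- function(elevations = c(0, 0.06, 0.13),
                                     config = NULL, groups = "NRM",
                                     ref_region = "CBWM", seed = 1) {
  out <- list()
  for (e in elevations) {
    cfg <- if (is.null(config)) {
      cohort_preset("ref_elevated", cereb_elevation = c(NRM = e, AE = e),
                    n_ae = 0)
    } else {
      config$cereb_elevation <- c(NRM = e, AE = e)
      config
    }
    coh <- generate_cohort(cfg, seed = seed, simulate_tacs = FALSE)
    st <- srtm_truth_table(coh, ref_region = ref_region)
    st <- st[!st$region %in% c("CBGM", "CBWM"), ]
    for (g in groups) {
      byreg <- dplyr::summarise(
        dplyr::group_by(st[st$group %in% c("HV", g), ], .data$region),
        direct_contrast = mean(.data$log_BPND_direct[.data$group == g]) -
          mean(.data$log_BPND_direct[.data$group == "HV"]),
        indirect_contrast = mean(.data$log_BPND_indirect[.data$group == g]) -
          mean(.data$log_BPND_indirect[.data$group == "HV"]),
        .groups = "drop"
      )
      byreg$elevation <- e
      byreg$group <- g
      byreg$shift <- byreg$indirect_contrast - byreg$direct_contrast
      out[[length(out) + 1]] <- byreg
    }
  }
  dplyr::bind_rows(out)
}
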