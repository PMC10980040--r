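#' Univariate linear mixed model on log binding potential
#'
#' The conventional comparison arm: a REML fit of
#' `log BP ~ region + sex + age + group:region + (1 | subject)`. Because no
#' group main effect is included, each `region:group` interaction
#' coefficient is the full group difference in that region (reference group
#' = first level, `HV` when present). Contrasts are reported as percent
#' differences `100 (exp(beta) - 1)` with Wald 80%/95% intervals.
#'
#' @param data A data frame with columns `subject_id`, `region`, `group`,
#'   `sex`, `age` and `log_bp` (at least two regions per subject).
#' @return A list of class `lme_result`: the fitted `lmerMod`, a tidy
#'   `contrasts` tibble, random-intercept and residual variances, and a
#'   `singular` flag (estimates are still returned when the fit is
#'   singular).
#' @export
fit_lme_logbp <- function(data) {
  need <- c("subject_id", "region", "group", "sex", "age", "log_bp")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (length(unique(data$region)) < 2) stop("need at least 2 regions")
  data <- as.data.frame(data)
  glev <- intersect(c("HV", "NRM", "AE"), unique(data$group))
  if (length(glev) == 0) glev <- unique(data$group)
  data$group <- factor(data$group, levels = glev)
  data$region <- factor(data$region, levels = unique(data$region))
  # constant covariates (e.g. a single-sex subsample) are dropped rather
  # than passed to the model as degenerate factors
  terms <- c("region",
             if (length(unique(data$sex)) > 1) "sex",
             if (length(unique(data$age)) > 1) "age",
             if (length(glev) > 1) "group:region")
  form <- stats::as.formula(paste("log_bp ~", paste(terms, collapse = " + "),
                                  "+ (1 | subject_id)"))
  fit <- lme4::lmer(form, data = data, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  lme4::.makeCC("ignore", tol = 1e-4)))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  ix <- grep(":group", names(fe))
  contrasts <- NULL
  if (length(ix)) {
    nm <- names(fe)[ix]
    region <- sub("^region([^:]+):group.*$", "\\1", nm)
    grp <- sub("^.*:group", "", nm)
    est <- unname(fe[ix]); s <- unname(se[ix])
    contrasts <- tibble::tibble(
      contrast = paste0(grp, "-", glev[1], ":", region),
      estimate = est, se = s,
      pct_diff = 100 * (exp(est) - 1),
      lo95 = 100 * (exp(est - 1.96 * s) - 1),
      hi95 = 100 * (exp(est + 1.96 * s) - 1),
      lo80 = 100 * (exp(est - 1.2816 * s) - 1),
      hi80 = 100 * (exp(est + 1.2816 * s) - 1)
    )
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(model = fit,
                 fixef = tibble::tibble(term = names(fe), estimate = unname(fe),
                                        se = unname(se)),
                 contrasts = contrasts,
                 var_subject = vc$vcov[vc$grp == "subject_id"],
                 var_residual = vc$vcov[vc$grp == "Residual"],
                 singular = singular),
            class = "lme_result")
}

#' One-way ANOVA of log plasma free fraction across groups
#'
#' Tests group differences in `log(f_P)` with a one-way ANOVA and reports
#' pairwise contrasts as percent differences `100 (exp(diff) - 1)` with
#' Tukey-adjusted p-values (set `adjust = "none"` for unadjusted).
#'
#' @param subjects A data frame with columns `group` and `fP_measured` (or a
#'   `log_fp` column, used as-is when present).
#' @param adjust `"tukey"` or `"none"`.
#' @return A list: `F`, `df` (length 2), `p`, `pairwise` tibble.
#' @export
fp_group_anova <- function(subjects, adjust = c("tukey", "none")) {
  adjust <- match.arg(adjust)
  y <- if ("log_fp" %in% names(subjects)) subjects$log_fp else {
    if (any(subjects$fP_measured <= 0)) stop("fP_measured must be positive")
    log(subjects$fP_measured)
  }
  g <- factor(subjects$group)
  tab <- table(g)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need at least 2 groups with at least 2 subjects each")
  }
  dat <- data.frame(y = y, g = g)
  av <- stats::aov(y ~ g, data = dat)
  s <- summary(av)[[1]]
  tk <- stats::TukeyHSD(av)$g
  diffs <- tk[, "diff"]
  pw <- tibble::tibble(
    comparison = rownames(tk),
    diff_log = unname(diffs),
    pct_diff = 100 * (exp(unname(diffs)) - 1),
    p = unname(tk[, "p adj"])
  )
  if (adjust == "none") {
    pw$p <- vapply(rownames(tk), function(cmp) {
      gg <- strsplit(cmp, "-", fixed = TRUE)[[1]]
      stats::t.test(y[g == gg[1]], y[g == gg[2]], var.equal = TRUE)$p.value
    }, numeric(1))
  }
  list(F = s[["F value"]][1], df = c(s[["Df"]][1], s[["Df"]][2]),
       p = s[["Pr(>F)"]][1], pairwise = pw)
}

#' Penalized smooth drift model for measured f_P
#'
#' Fits `log(f_P) ~ group + s(scan_date)` with a thin-plate regression
#' spline (basis dimension 10) and the smoothing penalty estimated by REML,
#' to ask whether apparent group differences in the plasma free fraction
#' survive adjustment for smooth experimental drift over the study period.
#'
#' @param subjects Data frame with `group`, `scan_date` and `fP_measured`
#'   (or `log_fp`); at least 20 subjects with distinct dates.
#' @param basis_dim Thin-plate basis dimension (default 10).
#' @return A list of class `drift_result`: approximate F and p for the
#'   smooth and for the group term, the smooth's effective df, the fitted
#'   smooth evaluated on a date grid, and the `gam` object.
#' @export
fp_drift_model <- function(subjects, basis_dim = 10) {
  y <- if ("log_fp" %in% names(subjects)) subjects$log_fp else {
    log(subjects$fP_measured)
  }
  dates <- subjects$scan_date
  if (length(unique(dates)) < 2) stop("all scan dates are identical")
  if (length(unique(dates)) < 20) stop("need at least 20 distinct scan dates")
  dat <- data.frame(y = y, scan_date = dates, group = factor(subjects$group))
  has_groups <- nlevels(dat$group) > 1
  form <- if (has_groups) {
    y ~ group + s(scan_date, k = basis_dim, bs = "tp")
  } else {
    y ~ s(scan_date, k = basis_dim, bs = "tp")
  }
  fit <- mgcv::gam(form, data = dat, method = "REML")
  sm <- summary(fit)
  grid <- seq(min(dates), max(dates), length.out = 100)
  nd <- data.frame(scan_date = grid, group = factor(levels(dat$group)[1],
                                                    levels = levels(dat$group)))
  pt <- stats::predict(fit, newdata = nd, type = "terms")
  smooth_col <- grep("scan_date", colnames(pt))
  structure(list(
    smooth_F = unname(sm$s.table[1, "F"]),
    smooth_p = unname(sm$s.table[1, "p-value"]),
    smooth_edf = unname(sm$s.table[1, "edf"]),
    group_F = if (has_groups) unname(sm$pTerms.table["group", "F"]) else NA_real_,
    group_p = if (has_groups) unname(sm$pTerms.table["group", "p-value"]) else NA_real_,
    basis_dim = basis_dim,
    smooth_grid = tibble::tibble(scan_date = grid,
                                 smooth = as.numeric(pt[, smooth_col])),
    model = fit
  ), class = "drift_result")
}
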