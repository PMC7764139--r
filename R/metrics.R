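#' Latent-scale intraclass correlation (ICC1)
#'
#' Proportion of total latent-scale variance attributable to the facility
#' level for a logistic model: `VG / (VG + pi^2/3)`. Values above 0.05 are
#' conventionally read as relevant between-provider variability.
#'
#' @param vg Facility (group) variance on the logit scale, `>= 0`.
#' @return ICC1 in `[0, 1)`.
#' @export
icc1 <- function(vg) {
  if (any(vg < 0)) stop("vg must be non-negative")
  vg / (vg + logit_residual_variance())
}

#' Group-mean reliability (ICC2)
#'
#' Reliability of the facility-level mean: the Spearman-Brown step-up of ICC1
#' by the number of facilities, `VG / (VG + (pi^2/3) / k)`. With `k = 1` it
#' reduces to ICC1.
#'
#' @param vg Facility variance on the logit scale, `>= 0`.
#' @param k Number of facilities, `>= 1`.
#' @return ICC2 in `[0, 1)`.
#' @export
icc2 <- function(vg, k) {
  if (any(vg < 0)) stop("vg must be non-negative")
  if (any(k < 1)) stop("k must be >= 1")
  vg / (vg + logit_residual_variance() / k)
}

#' Invert ICC1 back to a group variance
#'
#' Given an ICC1 on the latent logistic scale, returns the group variance
#' `VG = ICC1/(1-ICC1) * pi^2/3` that produces it. Useful to carry a reported
#' ICC1 into ICC2 or into simulation settings.
#'
#' @param icc ICC1 value in `[0, 1)`.
#' @return Group variance `VG`.
#' @export
vg_from_icc1 <- function(icc) {
  if (any(icc < 0 | icc >= 1)) stop("icc must be in [0, 1)")
  icc / (1 - icc) * logit_residual_variance()
}

#' Rankability of a quality indicator
#'
#' Share of between-facility heterogeneity attributable to true quality
#' differences rather than sampling noise: `rho = VG / (VG + median(s^2))`,
#' where the `s` are the standard errors of the facility effects from the
#' fixed-effects logistic model. Non-finite or non-estimable standard errors
#' are excluded from the median.
#'
#' @param vg Facility variance from the random-intercept model.
#' @param fe_ses Facility-effect standard errors (fixed model); `NA`/infinite
#'   entries are dropped.
#' @return Rankability in `[0, 1]`.
#' @export
rankability <- function(vg, fe_ses) {
  if (vg < 0) stop("vg must be non-negative")
  s <- fe_ses[is.finite(fe_ses)]
  if (!length(s)) stop("no finite facility standard errors")
  m <- median(s^2)
  if (vg == 0 && m == 0) return(0)
  vg / (vg + m)
}

#' Classify rankability into the conventional bands
#'
#' Low below 0.50, moderate from 0.50 to 0.75 inclusive, high above 0.75.
#'
#' @param rho Rankability in `[0, 1]`.
#' @return `"low"`, `"moderate"` or `"high"` (vectorised).
#' @export
classify_rankability <- function(rho) {
  if (any(rho < 0 | rho > 1)) stop("rho must be in [0, 1]")
  ifelse(rho < 0.50, "low", ifelse(rho <= 0.75, "moderate", "high"))
}

#' Parametric bootstrap confidence interval for ICC1 or ICC2
#'
#' Simulates outcomes from the fitted random-intercept model (new facility
#' effects from `N(0, VG)`, Bernoulli outcomes at the fitted linear
#' predictor), refits, recomputes the statistic, and returns the percentile
#' 2.5/97.5 interval. Refits are warm-started at the parent estimates.
#'
#' @param fit Converged [fit_random_intercept_logistic()] result.
#' @param statistic `"icc1"` or `"icc2"`.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed; the interval is reproducible given it.
#' @param quad_order Quadrature order for refits (default: the fit's order).
#' @return List with `lower`, `upper`, `estimate`, `n_boot`, `n_failed` and
#'   the vector of bootstrap `values`.
#' @export
bootstrap_ci <- function(fit, statistic = c("icc1", "icc2"), n_boot = 1000,
                         seed = 1L, quad_order = fit$quad_order) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!fit$converged) stop("fit did not converge")
  if (n_boot < 100) stop("n_boot must be >= 100")
  statistic <- match.arg(statistic)
  d <- fit$design
  k <- fit$n_groups
  eta <- drop(d$X %*% fit$beta)
  gidx <- as.integer(d$facility)
  stat_fun <- switch(statistic,
                     icc1 = function(f) icc1(f$vg),
                     icc2 = function(f) icc2(f$vg, f$n_groups))
  boot_spec <- model_spec(fit$spec$indicator, adjusters = fit$spec$adjusters,
                          outcome = ".y", facility = ".f")
  base <- data.frame(.f = d$facility)
  if (length(fit$spec$adjusters))
    base <- cbind(base, as.data.frame(d$X[, -1, drop = FALSE]))
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      u <- rnorm(k, 0, sqrt(fit$vg))
      ystar <- rbinom(length(eta), 1, plogis(eta + u[gidx]))
      bd <- base
      bd$.y <- ystar
      f <- tryCatch(
        fit_random_intercept_logistic(bd, boot_spec, quad_order = quad_order,
                                      start = list(beta = fit$beta,
                                                   vg = max(fit$vg, 1e-3))),
        error = function(e) NULL)
      if (is.null(f) || !f$converged) return(NA_real_)
      stat_fun(f)
    }, numeric(1))
  })
  n_failed <- sum(is.na(vals))
  if (n_failed > 0.2 * n_boot)
    stop(sprintf("bootstrap unstable: %d of %d refits failed",
                 n_failed, n_boot))
  ci <- quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(lower = ci[1], upper = ci[2],
       estimate = stat_fun(fit), n_boot = n_boot, n_failed = n_failed,
       values = vals)
}

#' Variability and reliability report for one fitted indicator
#'
#' Assembles the per-indicator profiling summary: ICC1 (with its relevance
#' flag at the 0.05 threshold), ICC2 with the facility count used, rankability
#' from the fixed-model standard errors with its band, and optional parametric
#' bootstrap confidence intervals.
#'
#' @param fit Converged random-intercept fit.
#' @param fe Fixed-effects facility table from [fit_fixed_effects_logistic()].
#' @param n_boot Bootstrap replicates for the ICC intervals; 0 skips them.
#' @param seed Seed for the bootstrap.
#' @return One-row data frame (class `qi_variability`) with columns
#'   `indicator`, `vg`, `icc1`, `icc1_low`, `icc1_high`, `icc1_relevant`,
#'   `icc2`, `icc2_low`, `icc2_high`, `rankability`, `rankability_class`,
#'   `median_s2`, `k`, `n_nonestimable`.
#' @export
variability_report <- function(fit, fe, n_boot = 0, seed = 1L) {
  stopifnot(inherits(fit, "glmm_fit"))
  ses <- fe$fe_se[fe$estimable]
  rho <- rankability(fit$vg, ses)
  ci1 <- ci2 <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    b1 <- bootstrap_ci(fit, "icc1", n_boot = n_boot, seed = seed)
    ci1 <- c(b1$lower, b1$upper)
    # ICC2 is a monotone transform of VG at fixed k: reuse the same draws
    vgs <- vg_from_icc1(b1$values[!is.na(b1$values)])
    ci2 <- quantile(icc2(vgs, fit$n_groups), c(0.025, 0.975), names = FALSE)
  }
  out <- data.frame(
    indicator = fit$indicator, vg = fit$vg,
    icc1 = icc1(fit$vg), icc1_low = ci1[1], icc1_high = ci1[2],
    icc1_relevant = icc1(fit$vg) > 0.05,
    icc2 = icc2(fit$vg, fit$n_groups), icc2_low = ci2[1], icc2_high = ci2[2],
    rankability = rho, rankability_class = classify_rankability(rho),
    median_s2 = median(ses^2), k = fit$n_groups,
    n_nonestimable = sum(!fe$estimable),
    stringsAsFactors = FALSE
  )
  class(out) <- c("qi_variability", "data.frame")
  out
}
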