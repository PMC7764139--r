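#' Risk-adjustment sets for each quality indicator
#'
#' Returns the canonical risk-adjuster set used when profiling facilities on a
#' given indicator: cognitive performance (CPS) and care level for every
#' indicator, age additionally for polypharmacy, and depression (DRS >= 3)
#' plus gender additionally for both pain indicators.
#'
#' @param indicator One of the ids returned by [indicator_ids()].
#' @return Character vector of coded covariate names (columns produced by
#'   [encode_adjusters()]).
#' @export
risk_adjusters <- function(indicator) {
  indicator <- match.arg(indicator, indicator_ids())
  base <- c("cps", "care_level")
  switch(indicator,
    polypharmacy = c(base, "age_dec"),
    pain_self = c(base, "depression", "female"),
    pain_observed = c(base, "depression", "female"),
    restraint_trunk = base,
    restraint_bedrails = base,
    weight_loss = base
  )
}

#' Model specification for one indicator
#'
#' Bundles the outcome/facility column names and the risk-adjuster set for a
#' random-intercept (or facility fixed-effects) logistic model. The default
#' adjusters follow [risk_adjusters()]; pass `adjusters` to override (e.g.
#' `character(0)` for an unadjusted model).
#'
#' @param indicator Indicator id.
#' @param adjusters Optional character vector of coded covariate columns.
#' @param outcome,facility Column names of the binary outcome and the facility
#'   identifier in the model data.
#' @return An object of class `qi_model_spec`.
#' @export
model_spec <- function(indicator, adjusters = NULL, outcome = "outcome",
                       facility = "facility_id") {
  indicator <- match.arg(indicator, indicator_ids())
  if (is.null(adjusters)) adjusters <- risk_adjusters(indicator)
  structure(list(indicator = indicator, adjusters = adjusters,
                 outcome = outcome, facility = facility),
            class = "qi_model_spec")
}

#' Code resident covariates for risk adjustment
#'
#' Produces the numeric covariates entering the models: `age_dec` (age in
#' decades centred at 85 years, from birth year and the export date), numeric
#' `care_level` and `cps` scores, `depression` (indicator of DRS >= 3, the
#' clinical cut for evidence of at least minor depression) and `female`.
#'
#' @param records Resident table (see [simulate_items()] for the schema).
#' @param export_date Date of the data export, used to compute age.
#' @return `records` with coded covariate columns appended.
#' @export
encode_adjusters <- function(records, export_date = as.Date("2017-08-01")) {
  stopifnot(all(c("birth_year", "sex", "care_level", "cps", "drs")
                %in% names(records)))
  yr <- as.integer(format(as.Date(export_date), "%Y"))
  records$age <- yr - records$birth_year
  records$age_dec <- (records$age - 85) / 10
  records$depression <- as.integer(records$drs >= 3)
  records$female <- as.integer(records$sex == "female")
  records
}

# Gauss-Hermite rule with pre-adjusted log-weights for adaptive quadrature.
gh_rule <- function(order) {
  stopifnot(order >= 1)
  r <- pracma::gaussHermite(order)
  list(x = r$x, logw_adj = log(r$w) + r$x^2)
}

# Assemble sorted y/X/group-offset arrays from a model data frame.
build_design <- function(data, spec) {
  need <- c(spec$outcome, spec$facility, spec$adjusters)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("model data lacks columns: ", paste(miss, collapse = ", "))
  data <- data[complete.cases(data[need]), need, drop = FALSE]
  y <- data[[spec$outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  fac <- factor(data[[spec$facility]])
  ord <- order(as.integer(fac))
  data <- data[ord, , drop = FALSE]
  y <- as.numeric(y[ord])
  fac <- fac[ord]
  X <- if (length(spec$adjusters))
    cbind(1, as.matrix(data[, spec$adjusters, drop = FALSE]))
  else matrix(1, nrow = nrow(data), ncol = 1)
  colnames(X) <- c("(Intercept)", spec$adjusters)
  idx <- as.integer(fac)
  starts <- match(seq_len(nlevels(fac)), idx) - 1L
  ends <- c(starts[-1] - 1L, length(idx) - 1L)
  list(y = y, X = X, facility = fac, grp_start = starts, grp_end = ends,
       levels = levels(fac))
}

#' Marginal log-likelihood of a random-intercept logistic model
#'
#' Evaluates the marginal log-likelihood at given parameter values, integrating
#' the facility random intercept out by adaptive Gauss-Hermite quadrature with
#' per-facility mode recentring. With `vg = 0` the model collapses to ordinary
#' logistic regression and the exact (integral-free) log-likelihood is
#' returned. Exposed mainly for diagnostics such as quadrature-order
#' convergence checks.
#'
#' @param beta Fixed-effect coefficients, intercept first, matching the columns
#'   of the design built from `spec` (intercept + adjusters in order).
#' @param vg Variance of the facility random intercept (latent/logit scale).
#' @param data Model data frame with outcome, facility and adjuster columns.
#' @param spec A [model_spec()].
#' @param quad_order Number of quadrature nodes (>= 1).
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(beta, vg, data, spec, quad_order = 15) {
  stopifnot(vg >= 0)
  d <- build_design(data, spec)
  if (length(beta) != ncol(d$X))
    stop("beta must have length ", ncol(d$X))
  if (vg == 0) {
    eta <- drop(d$X %*% beta)
    l1pe <- ifelse(eta > 30, eta, log1p(exp(eta)))  # stable log(1+e^eta)
    return(sum(d$y * eta - l1pe))
  }
  gh <- gh_rule(quad_order)
  agq_loglik_cpp(beta, log(vg), d$y, d$X, d$grp_start, d$grp_end,
                 gh$x, gh$logw_adj, FALSE)$loglik
}

#' Fit a risk-adjusted random-intercept logistic model
#'
#' Maximizes the marginal likelihood of a logistic model with one random
#' intercept per facility. The intercept is integrated out by adaptive
#' Gauss-Hermite quadrature (mode recentring per facility) and the outer
#' optimization runs over `(beta, log VG)` so the group variance stays
#' non-negative.
#'
#' @param data Model data frame; rows with missing outcome/adjusters are
#'   dropped (listwise deletion is expected upstream).
#' @param spec A [model_spec()].
#' @param quad_order Quadrature order (default 15; minimum 7 recommended).
#' @param start Optional warm start, `list(beta=, vg=)`.
#' @param maxit Maximum L-BFGS-B iterations.
#' @param factr L-BFGS-B convergence factor: iteration stops when the
#'   likelihood improvement drops below `factr` times machine epsilon.
#' @return A `glmm_fit` object: `beta`, `vg` (group variance \eqn{V_G}), `vr`
#'   (\eqn{\pi^2/3}), `loglik`, `n_groups`, `n_obs`, `converged`,
#'   `quad_order`, plus the internal design for empirical-Bayes and bootstrap
#'   computations.
#' @export
fit_random_intercept_logistic <- function(data, spec, quad_order = 15,
                                          start = NULL, maxit = 200,
                                          factr = 1e7) {
  d <- build_design(data, spec)
  k <- length(d$levels)
  if (k < 2) stop("need at least 2 facilities")
  if (all(d$y == 0) || all(d$y == 1))
    stop("degenerate data: outcome is constant (all ",
         d$y[1], "); variance components are not identifiable")
  gh <- gh_rule(quad_order)

  if (is.null(start)) {
    g0 <- suppressWarnings(
      glm.fit(d$X, d$y, family = binomial())
    )
    par0 <- c(g0$coefficients, log(0.5))
  } else {
    par0 <- c(start$beta, log(max(start$vg, 1e-6)))
  }
  p <- ncol(d$X)
  negll <- function(par) {
    -agq_loglik_cpp(par[seq_len(p)], par[p + 1L], d$y, d$X,
                    d$grp_start, d$grp_end, gh$x, gh$logw_adj, FALSE)$loglik
  }
  opt <- optim(par0, negll, method = "L-BFGS-B",
               lower = c(rep(-Inf, p), -15), upper = c(rep(Inf, p), 5),
               control = list(maxit = maxit, factr = factr))
  beta <- setNames(opt$par[seq_len(p)], colnames(d$X))
  vg <- unname(exp(opt$par[p + 1L]))
  if (vg < 1e-6) vg <- 0  # boundary: variance indistinguishable from zero
  structure(list(
    indicator = spec$indicator, beta = beta, vg = vg,
    vr = pi^2 / 3, loglik = -opt$value, n_groups = k,
    n_obs = length(d$y), converged = opt$convergence == 0L,
    quad_order = quad_order, spec = spec, design = d
  ), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Random-intercept logistic model (adaptive GH quadrature, order ",
      x$quad_order, ")\n", sep = "")
  cat(sprintf("indicator: %s | facilities: %d | residents: %d\n",
              x$indicator, x$n_groups, x$n_obs))
  cat(sprintf("logLik: %.4f | VG: %.4f | ICC1: %.4f | converged: %s\n",
              x$loglik, x$vg, icc1(x$vg), x$converged))
  print(round(x$beta, 4))
  invisible(x)
}

#' Empirical-Bayes facility effects
#'
#' Per-facility posterior mode of the random intercept given the data and the
#' maximum-likelihood estimates, with the conditional standard deviation taken
#' from the curvature of the posterior at the mode; 95% intervals are
#' `estimate +/- 1.96 * SD`. These are the shrunken effects displayed in
#' caterpillar plots.
#'
#' @param fit A converged [fit_random_intercept_logistic()] result.
#' @return Data frame with `facility_id`, `eb_estimate`, `eb_sd`, `conf_low`,
#'   `conf_high`.
#' @export
empirical_bayes_effects <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!fit$converged) stop("fit did not converge; refusing EB estimates")
  d <- fit$design
  gh <- gh_rule(fit$quad_order)
  res <- agq_loglik_cpp(fit$beta, log(max(fit$vg, 1e-12)), d$y, d$X,
                        d$grp_start, d$grp_end, gh$x, gh$logw_adj, TRUE)
  est <- if (fit$vg == 0) rep(0, length(d$levels)) else res$mode
  sdv <- res$cond_sd
  data.frame(facility_id = d$levels, eb_estimate = est, eb_sd = sdv,
             conf_low = est - 1.96 * sdv, conf_high = est + 1.96 * sdv,
             stringsAsFactors = FALSE)
}

#' Facility fixed-effects logistic model
#'
#' Ordinary logistic regression with sum-to-zero facility contrasts plus the
#' same risk adjusters as the random model. Each facility's effect is its
#' deviation from the (unweighted) mean facility, with a standard error `s`;
#' the squared errors `s^2` feed the rankability statistic. Facilities whose
#' outcome is constant (zero or all events) have no finite maximum-likelihood
#' effect; they are flagged `estimable = FALSE` and should be excluded from
#' `median(s^2)`.
#'
#' @param data Model data frame.
#' @param spec A [model_spec()].
#' @return Data frame with `facility_id`, `fe_estimate`, `fe_se`, `estimable`;
#'   attribute `n_nonestimable` counts flagged facilities.
#' @export
fit_fixed_effects_logistic <- function(data, spec) {
  d <- build_design(data, spec)
  k <- length(d$levels)
  if (k < 2) stop("need at least 2 facilities")
  fac <- d$facility
  ev <- tapply(d$y, fac, sum)
  nn <- tapply(d$y, fac, length)
  estimable <- ev > 0 & ev < nn

  # Facilities whose outcome is constant have no finite ML effect; keeping
  # them in a sum-to-zero fit lets their diverging coefficients contaminate
  # every facility's standard error, so their rows are dropped up front.
  keep_lv <- d$levels[estimable[d$levels]]
  if (length(keep_lv) < 2)
    stop("fewer than 2 facilities with non-degenerate outcomes")
  keep <- fac %in% keep_lv
  f2 <- factor(as.character(fac[keep]), levels = keep_lv)
  df <- data.frame(y = d$y[keep], facility = f2)
  Xc <- d$X[keep, -1, drop = FALSE]
  if (ncol(Xc)) df <- cbind(df, as.data.frame(Xc))
  form <- as.formula(paste("y ~ facility",
                           if (ncol(Xc)) paste("+", paste(colnames(Xc),
                                                          collapse = " + "))
                           else ""))
  fit <- suppressWarnings(
    glm(form, family = binomial(), data = df,
        contrasts = list(facility = "contr.sum"),
        control = list(maxit = 100, epsilon = 1e-12))
  )
  cf <- coef(fit)
  V <- vcov(fit)
  idx <- grep("^facility", names(cf))
  stopifnot(length(idx) == length(keep_lv) - 1)
  alpha <- cf[idx]
  eff <- c(alpha, -sum(alpha))
  Vff <- V[idx, idx, drop = FALSE]
  se <- c(sqrt(diag(Vff)), sqrt(sum(Vff)))
  out <- data.frame(facility_id = d$levels,
                    fe_estimate = NA_real_, fe_se = NA_real_,
                    estimable = unname(estimable[d$levels]),
                    stringsAsFactors = FALSE)
  m <- match(keep_lv, out$facility_id)
  out$fe_estimate[m] <- unname(eff)
  out$fe_se[m] <- unname(se)
  attr(out, "n_nonestimable") <- sum(!out$estimable)
  out
}

#' Combined facility-effect table
#'
#' Merges empirical-Bayes (random-model) and fixed-model facility effects into
#' one table, the shrinkage pairing used in diagnostics.
#'
#' @param eb Result of [empirical_bayes_effects()].
#' @param fe Result of [fit_fixed_effects_logistic()].
#' @return Merged data frame keyed by `facility_id`.
#' @export
facility_effects <- function(eb, fe) {
  merge(eb, fe, by = "facility_id", all = TRUE, sort = TRUE)
}
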