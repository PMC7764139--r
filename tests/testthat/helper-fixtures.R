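# Minimal schema-valid resident rows; override any field per test.
make_residents <- function(n = 1, facility_id = "F001", ...) {
  rec <- data.frame(
    facility_id = rep(facility_id, length.out = n),
    resident_id = sprintf("R%04d", seq_len(n)),
    birth_year = 1931L,
    admission_date = "2015-06-01",
    sex = "female",
    care_level = 6L,
    cps = 2L,
    drs = 1L,
    n_active_ingredients = 4L,
    pain_self_freq = "none",
    pain_self_intensity = "none",
    pain_obs_freq = "none",
    pain_obs_intensity = "none",
    trunk_restraint_daily = FALSE,
    trunk_restraint_context = "none",
    bedrails_daily_all_sides = FALSE,
    bedrail_context = "none",
    weight_loss_5pct_30d = FALSE,
    weight_loss_10pct_180d = FALSE,
    life_expectancy_lt6mo = "no",
    is_admission_assessment = FALSE,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# Independent dense-trapezoid oracle for the marginal log-likelihood of a
# random-intercept logistic model (integration over +/- 8 latent SD).
trapezoid_loglik <- function(beta, vg, data, spec, n_grid = 20001) {
  X <- cbind(1, as.matrix(data[, spec$adjusters, drop = FALSE]))
  eta <- drop(X %*% beta)
  y <- data[[spec$outcome]]
  tot <- 0
  for (f in unique(data[[spec$facility]])) {
    i <- data[[spec$facility]] == f
    u <- seq(-8 * sqrt(vg), 8 * sqrt(vg), length.out = n_grid)
    lg <- vapply(u, function(uu) {
      e <- eta[i] + uu
      sum(y[i] * e - log1p(exp(e)))
    }, numeric(1))
    integrand <- lg + dnorm(u, 0, sqrt(vg), log = TRUE)
    m <- max(integrand)
    tot <- tot + m + log(sum(exp(integrand - m)) * (u[2] - u[1]))
  }
  tot
}

small_glmm_fixture <- function(seed = 3) {
  cfg <- sim_config(n_facilities = 5, residents_per_facility = 20,
                    group_sd = 0.8, intercept = -0.5, seed = seed)
  simulate_outcomes(cfg, risk_set = c("cps", "care_level"))
}
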