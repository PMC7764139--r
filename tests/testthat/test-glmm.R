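spec2 <- model_spec("polypharmacy", adjusters = c("cps", "care_level"))

test_that("adaptive quadrature matches dense numerical integration", {
  d <- small_glmm_fixture(seed = 3)
  beta <- c(-0.4, 0.1, 0.05)
  for (vg in c(0.3, 0.6, 1.5)) {
    ll <- marginal_loglik(beta, vg, d, spec2, quad_order = 15)
    expect_lt(abs(ll - trapezoid_loglik(beta, vg, d, spec2)), 1e-6)
  }
  # quadrature-order convergence between 15 and 31 nodes
  expect_lt(abs(marginal_loglik(beta, 0.6, d, spec2, 15) -
                  marginal_loglik(beta, 0.6, d, spec2, 31)), 1e-6)
})

test_that("zero group variance collapses to ordinary logistic regression", {
  d <- small_glmm_fixture(seed = 5)
  g <- glm(outcome ~ cps + care_level, binomial, d)
  expect_equal(marginal_loglik(coef(g), 0, d, spec2),
               as.numeric(logLik(g)), tolerance = 1e-10)
  # and continuously: a tiny variance is numerically indistinguishable
  expect_lt(abs(marginal_loglik(coef(g), 1e-10, d, spec2) -
                  as.numeric(logLik(g))), 1e-4)
})

test_that("fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  cfg <- sim_config(n_facilities = 60, residents_per_facility = 50,
                    group_sd = 0.9, intercept = -1, seed = 11)
  d <- simulate_outcomes(cfg, risk_set = c("cps", "care_level"))
  f <- fit_random_intercept_logistic(d, spec2, quad_order = 15)
  expect_true(f$converged)
  expect_equal(f$vr, pi^2 / 3)
  m <- lme4::glmer(outcome ~ cps + care_level + (1 | facility_id), d,
                   binomial, nAGQ = 15)
  expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 1e-6)
  expect_equal(f$vg, unname(lme4::VarCorr(m)$facility_id[1]),
               tolerance = 1e-3)
  expect_equal(unname(f$beta), unname(lme4::fixef(m)), tolerance = 1e-3)

  eb <- empirical_bayes_effects(f)
  re <- lme4::ranef(m, condVar = TRUE)$facility_id
  expect_gt(cor(eb$eb_estimate, re[, 1]), 0.9999)
  expect_lt(max(abs(eb$eb_sd - sqrt(attr(re, "postVar")[1, 1, ]))), 1e-3)
})

test_that("degenerate inputs are refused loudly", {
  d <- small_glmm_fixture(seed = 3)
  d$outcome <- 0
  expect_error(fit_random_intercept_logistic(d, spec2), "degenerate")
  d1 <- small_glmm_fixture(seed = 3)
  d1 <- d1[d1$facility_id == d1$facility_id[1], ]
  expect_error(fit_random_intercept_logistic(d1, spec2), "2 facilities")
  expect_error(marginal_loglik(c(0, 0, 0), -1, small_glmm_fixture(3), spec2))
})

test_that("empirical Bayes estimates shrink the fixed-model effects", {
  cfg <- sim_config(n_facilities = 40, residents_per_facility = 60,
                    group_sd = 0.8, intercept = -0.8, seed = 17)
  d <- simulate_outcomes(cfg, risk_set = c("cps", "care_level"))
  f <- fit_random_intercept_logistic(d, spec2)
  eb <- empirical_bayes_effects(f)
  fe <- fit_fixed_effects_logistic(d, spec2)
  both <- facility_effects(eb, fe)
  both <- both[both$estimable, ]
  expect_gt(cor(both$eb_estimate, both$fe_estimate), 0.95)
  slope <- coef(lm(eb_estimate ~ fe_estimate, both))[2]
  expect_lt(slope, 1)
  # vanishing group variance pulls every EB estimate to zero
  f0 <- f
  f0$vg <- 0
  expect_true(all(empirical_bayes_effects(f0)$eb_estimate == 0))
})

test_that("fixed-effects facility estimates match a generic ML solver", {
  cfg <- sim_config(n_facilities = 4, residents_per_facility = 30,
                    group_sd = 0.7, intercept = -0.3, seed = 23)
  d <- simulate_outcomes(cfg, risk_set = "cps")
  spec1 <- model_spec("polypharmacy", adjusters = "cps")
  fe <- fit_fixed_effects_logistic(d, spec1)
  stopifnot(all(fe$estimable))

  # independent route: explicit sum-to-zero dummy design + quasi-Newton ML
  fac <- factor(d$facility_id)
  Z <- model.matrix(~fac, contrasts.arg = list(fac = "contr.sum"))
  X <- cbind(Z, cps = d$cps)
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(d$outcome * eta - log1p(exp(eta)))
  }
  o <- optim(rep(0, ncol(X)), nll, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-14))
  o <- optim(o$par, nll, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-15))
  alpha <- o$par[2:4]
  expect_lt(max(abs(fe$fe_estimate - c(alpha, -sum(alpha)))), 1e-6)
})

test_that("fixed-model facility effects are symmetric and root-n consistent", {
  # two identical facilities at rate 1/2 have zero effects
  rec <- data.frame(facility_id = rep(c("A", "B"), each = 4),
                    outcome = rep(c(0, 1), 4), cps = 2)
  spec0 <- model_spec("polypharmacy", adjusters = character(0))
  fe <- fit_fixed_effects_logistic(rec, spec0)
  expect_equal(fe$fe_estimate, c(0, 0), tolerance = 1e-8)

  # quadrupling the facility size halves the standard errors
  se_at <- function(m, seed) {
    cfg <- sim_config(n_facilities = 30, residents_per_facility = m,
                      group_sd = 0.5, intercept = -0.5, seed = seed)
    d <- simulate_outcomes(cfg)
    median(fit_fixed_effects_logistic(d, spec0)$fe_se, na.rm = TRUE)
  }
  ratio <- se_at(50, 101) / se_at(200, 101)
  expect_lt(abs(ratio - 2), 0.2)

  # facilities with constant outcomes are flagged, not poisoning the rest
  rec2 <- data.frame(facility_id = rep(c("A", "B", "C"), each = 20),
                     outcome = c(rep(0:1, 10), rep(0:1, 10), rep(0, 20)))
  fe2 <- fit_fixed_effects_logistic(rec2, spec0)
  expect_false(fe2$estimable[fe2$facility_id == "C"])
  expect_true(all(is.finite(fe2$fe_se[fe2$estimable])))
  expect_true(all(fe2$fe_se[fe2$estimable] < 1))
})

test_that("recentring a covariate changes only the intercept", {
  d <- small_glmm_fixture(seed = 29)
  f1 <- fit_random_intercept_logistic(d, spec2, factr = 1e2)
  d2 <- d
  d2$cps <- d2$cps + 10
  b0 <- f1$beta
  b0[1] <- b0[1] - 10 * b0["cps"]
  f2 <- fit_random_intercept_logistic(d2, spec2, factr = 1e2,
                                      start = list(beta = b0, vg = f1$vg))
  expect_equal(f2$beta[["cps"]], f1$beta[["cps"]], tolerance = 1e-6)
  expect_equal(f2$beta[["care_level"]], f1$beta[["care_level"]],
               tolerance = 1e-6)
  expect_equal(f2$vg, f1$vg, tolerance = 1e-6)
  expect_equal(f2$beta[[1]], f1$beta[[1]] - 10 * f1$beta[["cps"]],
               tolerance = 1e-5)
})
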