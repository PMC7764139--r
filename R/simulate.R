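# Default covariate distributions: age and sex match the study population
# summary (mean 86.1, SD 8.36, 72.8% female); care level, CPS and DRS are
# categorical with masses chosen to reproduce the reported medians (care level
# median 6, IQR 4-9) and a plausible severity mix. All are configurable.
default_covariate_params <- function() {
  list(
    age = list(mean = 86.1, sd = 8.36, min = 65, max = 110),
    female_prob = 0.728,
    care_level = list(probs = prop.table(dnorm(1:12, mean = 6.3, sd = 2.8))),
    cps = list(probs = prop.table(dnorm(0:6, mean = 2.4, sd = 1.9))),
    drs = list(probs = prop.table(dnbinom(0:14, size = 2, mu = 2.2))),
    los = list(meanlog = log(859), sdlog = 1.10),  # stay length, days
    export_date = "2017-08-01"
  )
}

# Default per-indicator marginal prevalence targets (facility-mean scale) and
# latent facility SDs. The SDs correspond, through ICC1 = VG/(VG + pi^2/3),
# to the intraclass correlations reported for the six Swiss indicators.
default_indicator_params <- function() {
  icc <- c(polypharmacy = 0.068, pain_self = 0.134, pain_observed = 0.223,
           restraint_trunk = 0.396, restraint_bedrails = 0.371,
           weight_loss = 0.137)
  list(
    prevalence = c(polypharmacy = 0.430, pain_self = 0.197,
                   pain_observed = 0.149, restraint_trunk = 0.034,
                   restraint_bedrails = 0.130, weight_loss = 0.079),
    group_sd = sqrt(vg_from_icc1(icc)),
    # mild case-mix effects (logit scale) so that risk adjustment matters
    coefs = list(
      polypharmacy = c(care_level = 0.08, cps = -0.10, age_dec = -0.10),
      pain_self = c(care_level = 0.06, cps = -0.15, depression = 0.35,
                    female = 0.15),
      pain_observed = c(care_level = 0.06, cps = 0.10, depression = 0.30,
                        female = 0.10),
      restraint_trunk = c(care_level = 0.15, cps = 0.30),
      restraint_bedrails = c(care_level = 0.12, cps = 0.25),
      weight_loss = c(care_level = 0.08, cps = 0.12)
    ),
    consent_prob = c(restraint_trunk = 0.02, restraint_bedrails = 0.04),
    admission_assessment_prob = 0.05,
    life_expectancy_probs = c(yes = 0.03, no = 0.92, not_collected = 0.05)
  )
}

default_missingness <- function() {
  c(pain_self = 0.134, pain_observed = 0.007,
    restraint_bedrails = 0.016, weight_loss = 0.001)
}

#' Simulation configuration
#'
#' Validated settings for the synthetic resident-population generators. The
#' defaults emulate the study conditions: 152 facilities of 75 residents
#' (about 11,400 residents), age ~ normal(86.1, 8.36) truncated to [65, 110],
#' 72.8% female, care level 1-12, CPS 0-6, DRS 0-14, and 13.4% invalid
#' self-reported pain answers.
#'
#' @param n_facilities Number of facilities (>= 1).
#' @param residents_per_facility Scalar size, or length-2 range from which
#'   each facility's size is drawn uniformly.
#' @param group_sd SD of the facility random intercept on the logit scale
#'   (so `VG = group_sd^2`); used by [simulate_outcomes()].
#' @param intercept Fixed intercept on the logit scale ([simulate_outcomes()]).
#' @param fixed_effects Named numeric vector of logit-scale coefficients on
#'   the coded covariates (`cps`, `care_level`, `age_dec`, `depression`,
#'   `female`).
#' @param covariate_params Distribution parameters; see
#'   `qiprofile:::default_covariate_params()` for the structure.
#' @param indicator_params Item-generator steering (per-indicator prevalence
#'   targets, facility SDs, case-mix coefficients, consent and exclusion
#'   rates); see `qiprofile:::default_indicator_params()`.
#' @param missingness_rates Named probabilities of invalid/missing items per
#'   indicator (default: self-reported pain 0.134, observed pain 0.007,
#'   bedrails 0.016, weight loss 0.001).
#' @param seed Integer root seed. Sub-seeds are derived per random stream
#'   (facility effects, covariates, outcomes, items, consent, exclusions,
#'   missingness) so adding a stream does not shift the others.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_facilities = 152, residents_per_facility = 75,
                       group_sd = 0.7, intercept = -1,
                       fixed_effects = c(cps = 0.15, care_level = 0.08,
                                         age_dec = 0.20, depression = 0.30,
                                         female = 0.10),
                       covariate_params = list(),
                       indicator_params = list(),
                       missingness_rates = NULL, seed = 1L) {
  cp <- modifyList(default_covariate_params(), covariate_params)
  ip <- modifyList(default_indicator_params(), indicator_params)
  mr <- default_missingness()
  if (!is.null(missingness_rates)) {
    bad <- setdiff(names(missingness_rates), indicator_ids())
    if (length(bad)) stop("unknown missingness item(s): ",
                          paste(bad, collapse = ", "))
    mr[names(missingness_rates)] <- missingness_rates
  }
  stopifnot(
    length(n_facilities) == 1, n_facilities >= 1,
    length(residents_per_facility) %in% c(1, 2),
    all(residents_per_facility >= 1),
    length(group_sd) == 1, group_sd >= 0,
    is.numeric(intercept), length(intercept) == 1,
    all(mr >= 0 & mr <= 1),
    cp$female_prob >= 0, cp$female_prob <= 1,
    all(ip$prevalence > 0 & ip$prevalence < 1),
    all(ip$group_sd >= 0),
    length(seed) == 1, is.finite(seed)
  )
  if (!is.null(names(fixed_effects)) || length(fixed_effects) == 0) {
    bad <- setdiff(names(fixed_effects), coded_covariate_names())
    if (length(bad)) stop("unknown fixed-effect covariate(s): ",
                          paste(bad, collapse = ", "))
  } else stop("fixed_effects must be a named numeric vector")
  structure(list(
    n_facilities = as.integer(n_facilities),
    residents_per_facility = as.integer(residents_per_facility),
    group_sd = group_sd, intercept = intercept,
    fixed_effects = fixed_effects, covariate_params = cp,
    indicator_params = ip, missingness_rates = mr,
    seed = as.integer(seed)
  ), class = "sim_config")
}

coded_covariate_names <- function() {
  c("cps", "care_level", "age_dec", "depression", "female")
}

#' Read a simulation configuration from YAML
#'
#' Loads a YAML file whose top-level keys mirror the arguments of
#' [sim_config()] and validates it; unknown keys raise an error.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(sim_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  for (nm in c("fixed_effects", "missingness_rates"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(sim_config, raw)
}

# facility sizes and ids
draw_sizes <- function(config) {
  rp <- config$residents_per_facility
  if (length(rp) == 1) rep(rp, config$n_facilities)
  else with_seed(stream_seed(config$seed, "facility") + 1L,
                 sample(rp[1]:rp[2], config$n_facilities, replace = TRUE))
}

# resident-level covariate draws (stream: covariates)
draw_covariates <- function(config, sizes) {
  cp <- config$covariate_params
  n <- sum(sizes)
  k <- config$n_facilities
  facility_id <- rep(sprintf("F%03d", seq_len(k)), sizes)
  with_seed(stream_seed(config$seed, "covariates"), {
    # truncated-normal age via inverse-CDF
    lo <- pnorm(cp$age$min, cp$age$mean, cp$age$sd)
    hi <- pnorm(cp$age$max, cp$age$mean, cp$age$sd)
    age <- qnorm(runif(n, lo, hi), cp$age$mean, cp$age$sd)
    sex <- ifelse(runif(n) < cp$female_prob, "female", "male")
    care_level <- sample(1:12, n, replace = TRUE, prob = cp$care_level$probs)
    cps <- sample(0:6, n, replace = TRUE, prob = cp$cps$probs)
    drs <- sample(0:14, n, replace = TRUE, prob = cp$drs$probs)
    los <- pmax(1, round(rlnorm(n, cp$los$meanlog, cp$los$sdlog)))
    export <- as.Date(cp$export_date)
    data.frame(
      facility_id = facility_id,
      resident_id = sprintf("%s-R%05d", facility_id,
                            sequence(sizes)),
      birth_year = as.integer(format(export, "%Y")) - round(age),
      admission_date = format(export - los, "%Y-%m-%d"),
      sex = sex, care_level = care_level, cps = cps, drs = drs,
      stringsAsFactors = FALSE
    )
  })
}

# Solve the logit intercept a so that the population-average event probability
# E[ plogis(a + offset + sigma*Z) ] hits `target` (Gauss-Hermite over Z).
calibrate_intercept <- function(target, offsets, sigma, order = 21) {
  r <- pracma::gaussHermite(order)
  w <- r$w / sqrt(pi)
  z <- sqrt(2) * r$x
  f <- function(a) {
    p <- vapply(seq_along(z),
                function(j) mean(plogis(a + offsets + sigma * z[j])),
                numeric(1))
    sum(w * p) - target
  }
  uniroot(f, c(-15, 15), tol = 1e-10)$root
}

#' Simulate binary outcomes from a known random-intercept logistic model
#'
#' Direct generator for metric-recovery studies: facility intercepts are drawn
#' from `N(0, group_sd^2)`, covariates from the configured distributions, and
#' outcomes from `Bernoulli(plogis(intercept + X beta + facility effect))`.
#' The true facility effect is attached per row so estimators can be checked
#' against the latent truth.
#'
#' @param config A [sim_config()].
#' @param risk_set Character vector of coded covariate names entering the
#'   linear predictor (subset of `cps`, `care_level`, `age_dec`, `depression`,
#'   `female`); empty for an intercept-only model.
#' @return Data frame with facility/resident ids, coded covariates, the true
#'   `facility_effect` and the binary `outcome`.
#' @export
simulate_outcomes <- function(config, risk_set = character(0)) {
  stopifnot(inherits(config, "sim_config"))
  bad <- setdiff(risk_set, coded_covariate_names())
  if (length(bad)) stop("unknown covariate(s) in risk_set: ",
                        paste(bad, collapse = ", "))
  sizes <- draw_sizes(config)
  cov <- draw_covariates(config, sizes)
  cov <- encode_adjusters(cov, config$covariate_params$export_date)
  u <- with_seed(stream_seed(config$seed, "facility"),
                 rnorm(config$n_facilities, 0, config$group_sd))
  eta <- rep(config$intercept, nrow(cov))
  for (v in risk_set) {
    b <- config$fixed_effects[[v]]
    if (is.null(b)) stop("no fixed effect configured for covariate: ", v)
    eta <- eta + b * cov[[v]]
  }
  g <- rep(seq_len(config$n_facilities), sizes)
  eta <- eta + u[g]
  cov$facility_effect <- u[g]
  cov$outcome <- with_seed(stream_seed(config$seed, "outcomes"),
                           rbinom(nrow(cov), 1, plogis(eta)))
  cov
}

# helper: vectorised categorical sampling with fixed probs
rcat <- function(n, levels, probs) {
  levels[sample.int(length(levels), n, replace = TRUE, prob = probs)]
}

#' Simulate a full resident-item population
#'
#' Generates one row per resident with every raw item needed by the six
#' quality indicators. Each indicator's latent event propensity follows a
#' random-intercept logistic model (facility SDs and marginal prevalence
#' targets from `indicator_params`; intercepts calibrated so the realised
#' prevalences land on the targets), and the latent event is then translated
#' into raw items (ingredient counts, pain frequency/intensity scales,
#' restraint flags and consent contexts, weight-loss flags). Invalid/missing
#' items are injected at `missingness_rates`.
#'
#' @param config A [sim_config()].
#' @return Data frame of resident records (one per resident). The matrix of
#'   true latent facility effects is attached as attribute
#'   `facility_effects`, the calibrated intercepts as `intercepts`.
#' @export
simulate_items <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ip <- config$indicator_params
  sizes <- draw_sizes(config)
  rec <- draw_covariates(config, sizes)
  cov <- encode_adjusters(rec, config$covariate_params$export_date)
  n <- nrow(rec)
  k <- config$n_facilities
  g <- rep(seq_len(k), sizes)
  ids <- indicator_ids()

  # exclusion-context items, independent of the latent outcomes
  excl <- with_seed(stream_seed(config$seed, "exclusions"), {
    list(adm = runif(n) < ip$admission_assessment_prob,
         le = rcat(n, names(ip$life_expectancy_probs),
                   ip$life_expectancy_probs))
  })
  rec$is_admission_assessment <- excl$adm
  rec$life_expectancy_lt6mo <- excl$le

  U <- with_seed(stream_seed(config$seed, "facility"), {
    matrix(rnorm(k * length(ids)), k, length(ids),
           dimnames = list(NULL, ids))
  })
  U <- sweep(U, 2, ip$group_sd[ids], `*`)

  # latent event per indicator
  intercepts <- setNames(numeric(length(ids)), ids)
  out <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  offs <- lapply(ids, function(id) {
    co <- ip$coefs[[id]]
    off <- numeric(n)
    for (v in names(co)) off <- off + co[[v]] * cov[[v]]
    off
  })
  names(offs) <- ids
  for (id in ids)
    intercepts[id] <- calibrate_intercept(ip$prevalence[[id]], offs[[id]],
                                          ip$group_sd[[id]])
  out[] <- with_seed(stream_seed(config$seed, "items"), {
    vapply(ids, function(id) {
      rbinom(n, 1, plogis(intercepts[id] + offs[[id]] + U[g, id]))
    }, integer(n))
  })

  cons <- with_seed(stream_seed(config$seed, "consent"), {
    list(trunk = runif(n) < ip$consent_prob[["restraint_trunk"]],
         rail = runif(n) < ip$consent_prob[["restraint_bedrails"]])
  })

  with_seed(stream_seed(config$seed, "items") + 1L, {
    # polypharmacy: ingredient count either side of the 9-ingredient cut
    po <- out[, "polypharmacy"] == 1
    rec$n_active_ingredients <- ifelse(po, 9L + rpois(n, 2.5),
                                       rbinom(n, 8, 0.45))

    draw_pain <- function(event) {
      freq <- character(n); intens <- character(n)
      ev <- which(event == 1); nev <- which(event == 0)
      daily <- runif(length(ev)) < 0.85
      freq[ev] <- ifelse(daily, "daily", "nondaily")
      intens[ev] <- ifelse(daily,
                           rcat(length(ev), c("moderate", "strong",
                                              "very_strong_unbearable"),
                                c(0.55, 0.30, 0.15)),
                           "very_strong_unbearable")
      f0 <- rcat(length(nev), c("none", "nondaily", "daily"),
                 c(0.62, 0.28, 0.10))
      freq[nev] <- f0
      intens[nev] <- ifelse(f0 == "none", "none",
                            ifelse(f0 == "daily", "mild",
                                   rcat(length(nev),
                                        c("mild", "moderate", "strong"),
                                        c(0.5, 0.35, 0.15))))
      list(freq = freq, intens = intens)
    }
    ps <- draw_pain(out[, "pain_self"])
    rec$pain_self_freq <- ps$freq
    rec$pain_self_intensity <- ps$intens
    pob <- draw_pain(out[, "pain_observed"])
    rec$pain_obs_freq <- pob$freq
    rec$pain_obs_intensity <- pob$intens

    restr <- function(event, consent) {
      use <- consent | event == 1
      ctx <- rep("none", n)
      ctx[consent] <- "capable_agreed"
      ne <- which(!consent & event == 1)
      ctx[ne] <- rcat(length(ne), c("incapable", "not_clarified"),
                      c(0.8, 0.2))
      list(use = use, ctx = ctx)
    }
    tr <- restr(out[, "restraint_trunk"], cons$trunk)
    rec$trunk_restraint_daily <- tr$use
    rec$trunk_restraint_context <- tr$ctx
    br <- restr(out[, "restraint_bedrails"], cons$rail)
    rec$bedrails_daily_all_sides <- br$use
    rec$bedrail_context <- br$ctx

    wl <- out[, "weight_loss"] == 1
    typ <- rcat(n, c("w30", "w180", "both"), c(0.45, 0.40, 0.15))
    rec$weight_loss_5pct_30d <- wl & typ %in% c("w30", "both")
    rec$weight_loss_10pct_180d <- wl & typ %in% c("w180", "both")
    rec
  }) -> rec

  mr <- config$missingness_rates
  rec <- with_seed(stream_seed(config$seed, "missingness"), {
    if (mr[["pain_self"]] > 0) {
      inv <- runif(n) < mr[["pain_self"]]
      what <- rcat(n, c("freq", "intens", "both"), c(0.45, 0.45, 0.10))
      rec$pain_self_freq[inv & what != "intens"] <- "invalid"
      rec$pain_self_intensity[inv & what != "freq"] <- "invalid"
    }
    if (mr[["pain_observed"]] > 0) {
      na <- runif(n) < mr[["pain_observed"]]
      rec$pain_obs_freq[na] <- NA
      rec$pain_obs_intensity[na] <- NA
    }
    if (mr[["restraint_bedrails"]] > 0)
      rec$bedrails_daily_all_sides[runif(n) < mr[["restraint_bedrails"]]] <- NA
    if (mr[["weight_loss"]] > 0) {
      na <- runif(n) < mr[["weight_loss"]]
      rec$weight_loss_5pct_30d[na] <- NA
      rec$weight_loss_10pct_180d[na] <- NA
    }
    rec
  })

  rec <- rec[, setdiff(names(rec),
                       c("age", "age_dec", "depression", "female"))]
  attr(rec, "facility_effects") <- U
  attr(rec, "intercepts") <- intercepts
  rec
}

#' Write / read resident tables as delimited text
#'
#' Comma-separated, header row, UTF-8, ISO-8601 dates — the interchange format
#' between the generator and the indicator engine.
#'
#' @param records Resident data frame.
#' @param path File path.
#' @return `read_residents()` returns the resident data frame.
#' @export
write_residents <- function(records, path) {
  write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8",
            na = "")
  invisible(path)
}

#' @rdname write_residents
#' @export
read_residents <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  na.strings = "")
  for (v in c("trunk_restraint_daily", "bedrails_daily_all_sides",
              "weight_loss_5pct_30d", "weight_loss_10pct_180d",
              "is_admission_assessment"))
    if (v %in% names(rec)) rec[[v]] <- as.logical(rec[[v]])
  rec
}
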