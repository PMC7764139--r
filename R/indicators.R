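#' Quality-indicator identifiers
#'
#' The six indicators: polypharmacy (>= 9 active ingredients in 7 days),
#' self-reported and observed pain (daily moderate-or-higher, or nondaily
#' very strong/unbearable), trunk-fixation/seating restraint, bedrail
#' restraint (daily, all open sides), and weight loss (>= 5% in 30 days or
#' >= 10% in 180 days).
#'
#' @return Character vector of indicator ids.
#' @export
indicator_ids <- function() {
  c("polypharmacy", "pain_self", "pain_observed",
    "restraint_trunk", "restraint_bedrails", "weight_loss")
}

pain_freq_levels <- c("none", "nondaily", "daily")
pain_intensity_levels <- c("none", "mild", "moderate", "strong",
                           "very_strong_unbearable")
moderate_or_higher <- c("moderate", "strong", "very_strong_unbearable")
context_levels <- c("capable_agreed", "incapable", "not_clarified", "none")

#' Validate a resident table against the input schema
#'
#' Checks column presence, types and value ranges (care level 1-12, CPS 0-6,
#' DRS 0-14, pain scales, restraint contexts, logical flags). The first
#' violation raises an error naming the row and field.
#'
#' @param records Resident data frame.
#' @return `records`, invisibly, if valid.
#' @export
validate_residents <- function(records) {
  need <- c("facility_id", "resident_id", "birth_year", "admission_date",
            "sex", "care_level", "cps", "drs", "n_active_ingredients",
            "pain_self_freq", "pain_self_intensity", "pain_obs_freq",
            "pain_obs_intensity", "trunk_restraint_daily",
            "trunk_restraint_context", "bedrails_daily_all_sides",
            "bedrail_context", "weight_loss_5pct_30d",
            "weight_loss_10pct_180d", "life_expectancy_lt6mo",
            "is_admission_assessment")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))

  fail <- function(col, bad) {
    if (any(bad, na.rm = TRUE))
      stop(sprintf("schema violation in field '%s' at row %d (value: %s)",
                   col, which(bad)[1],
                   format(records[[col]][which(bad)[1]])))
  }
  fail("care_level", !records$care_level %in% 1:12)
  fail("cps", !records$cps %in% 0:6)
  fail("drs", !records$drs %in% 0:14)
  fail("sex", !records$sex %in% c("female", "male"))
  fail("n_active_ingredients",
       !is.na(records$n_active_ingredients) & records$n_active_ingredients < 0)
  ok_or_na0 <- function(x, levels) !is.na(x) & !x %in% levels
  fail("pain_self_freq",
       ok_or_na0(records$pain_self_freq, c(pain_freq_levels, "invalid")))
  fail("pain_self_intensity",
       ok_or_na0(records$pain_self_intensity,
                 c(pain_intensity_levels, "invalid")))
  ok_or_na <- function(x, levels) !is.na(x) & !x %in% levels
  fail("pain_obs_freq", ok_or_na(records$pain_obs_freq, pain_freq_levels))
  fail("pain_obs_intensity",
       ok_or_na(records$pain_obs_intensity, pain_intensity_levels))
  fail("trunk_restraint_context",
       ok_or_na(records$trunk_restraint_context, context_levels))
  fail("bedrail_context", ok_or_na(records$bedrail_context, context_levels))
  fail("life_expectancy_lt6mo",
       ok_or_na(records$life_expectancy_lt6mo,
                c("yes", "no", "not_collected")))
  for (v in c("trunk_restraint_daily", "bedrails_daily_all_sides",
              "weight_loss_5pct_30d", "weight_loss_10pct_180d",
              "is_admission_assessment"))
    fail(v, !is.na(records[[v]]) & !is.logical(records[[v]]))
  # a restraint context of "none" implies the use flag is false
  fail("trunk_restraint_daily",
       records$trunk_restraint_context == "none" &
         records$trunk_restraint_daily)
  fail("bedrails_daily_all_sides",
       records$bedrail_context == "none" & records$bedrails_daily_all_sides)
  invisible(records)
}

pain_outcome <- function(freq, intensity) {
  (freq == "daily" & intensity %in% moderate_or_higher) |
    (freq == "nondaily" & intensity == "very_strong_unbearable")
}

#' Extract one indicator's eligibility and outcome per resident
#'
#' Applies the indicator's exclusion criteria first, then listwise deletion of
#' residents with missing required items, and evaluates the numerator
#' predicate on the remaining (eligible) residents:
#' * `polypharmacy` — no exclusions; outcome = 9 or more active ingredients.
#' * `pain_self` — excluded if the frequency or intensity answer is invalid;
#'   outcome = daily moderate-or-higher pain, or nondaily very strong pain.
#' * `pain_observed` — same predicate on observed items, no exclusions.
#' * `restraint_trunk` / `restraint_bedrails` — excluded if a resident capable
#'   of judgment requested/agreed to the measure; outcome = daily use.
#' * `weight_loss` — excluded if life expectancy is judged under 6 months or
#'   the last assessment was the admission assessment; outcome = loss of >= 5%
#'   in 30 days or >= 10% in 180 days.
#'
#' @param records Resident table (validated against the schema).
#' @param id Indicator id.
#' @param exclude_unclarified_context If `TRUE`, restraint cases whose consent
#'   context is not yet clarified are also excluded (default keeps them in the
#'   denominator; only an affirmative agreement by a resident capable of
#'   judgment excludes).
#' @return Data frame with `facility_id`, `resident_id`, `eligible`,
#'   `outcome` (0/1, `NA` when not eligible) and `exclusion_reason`
#'   (`"none"`, `"consented"`, `"invalid_answer"`, `"life_expectancy"`,
#'   `"admission_assessment"`, `"unclarified_context"`, `"missing_item"`).
#' @export
extract_indicator <- function(records, id, exclude_unclarified_context = FALSE) {
  id <- match.arg(id, indicator_ids())
  validate_residents(records)
  n <- nrow(records)
  reason <- rep("none", n)
  outcome <- rep(NA, n)

  mark <- function(reason_now, cond, label) {
    ifelse(reason_now == "none" & cond %in% TRUE, label, reason_now)
  }
  if (id == "polypharmacy") {
    reason <- mark(reason, is.na(records$n_active_ingredients), "missing_item")
    outcome <- records$n_active_ingredients >= 9
  } else if (id %in% c("pain_self", "pain_observed")) {
    fr <- if (id == "pain_self") records$pain_self_freq else
      records$pain_obs_freq
    it <- if (id == "pain_self") records$pain_self_intensity else
      records$pain_obs_intensity
    if (id == "pain_self")
      reason <- mark(reason, fr == "invalid" | it == "invalid",
                     "invalid_answer")
    reason <- mark(reason, is.na(fr) | is.na(it), "missing_item")
    outcome <- pain_outcome(fr, it)
  } else if (id %in% c("restraint_trunk", "restraint_bedrails")) {
    use <- if (id == "restraint_trunk") records$trunk_restraint_daily else
      records$bedrails_daily_all_sides
    ctx <- if (id == "restraint_trunk") records$trunk_restraint_context else
      records$bedrail_context
    reason <- mark(reason, ctx == "capable_agreed", "consented")
    if (exclude_unclarified_context)
      reason <- mark(reason, ctx == "not_clarified", "unclarified_context")
    reason <- mark(reason, is.na(use) | is.na(ctx), "missing_item")
    outcome <- use
  } else if (id == "weight_loss") {
    reason <- mark(reason, records$life_expectancy_lt6mo == "yes",
                   "life_expectancy")
    reason <- mark(reason, records$is_admission_assessment,
                   "admission_assessment")
    reason <- mark(reason, is.na(records$weight_loss_5pct_30d) |
                     is.na(records$weight_loss_10pct_180d), "missing_item")
    outcome <- records$weight_loss_5pct_30d | records$weight_loss_10pct_180d
  }
  eligible <- reason == "none"
  data.frame(
    facility_id = records$facility_id,
    resident_id = records$resident_id,
    eligible = eligible,
    outcome = ifelse(eligible, as.integer(outcome), NA_integer_),
    exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Extract all six indicators
#'
#' @param records Resident table.
#' @param ids Indicator subset (default all six).
#' @param ... Passed to [extract_indicator()].
#' @return Named list of extract tables.
#' @export
extract_all_indicators <- function(records, ids = indicator_ids(), ...) {
  setNames(lapply(ids, function(id) extract_indicator(records, id, ...)), ids)
}

#' Per-facility indicator rates
#'
#' Aggregates an extract into each facility's eligible count, event count and
#' rate, plus the cross-facility summary. The headline prevalence is the
#' unweighted mean of facility rates with its SD; the resident-level pooled
#' rate is also reported. Facilities with zero eligible residents get an
#' undefined (`NA`) rate and are flagged.
#'
#' @param extracts Extract table from [extract_indicator()].
#' @param indicator Optional indicator id recorded in the result.
#' @return Object of class `facility_rates`: list with `by_facility` (data
#'   frame `facility_id`, `n_eligible`, `n_events`, `rate`, `undefined`),
#'   `prevalence_mean`, `prevalence_sd`, `pooled_rate`, `indicator`.
#' @export
facility_rates <- function(extracts, indicator = NA_character_) {
  if (!nrow(extracts)) stop("empty extract")
  if (!any(extracts$eligible)) stop("no eligible residents in any facility")
  fac <- unique(extracts$facility_id)
  el <- extracts[extracts$eligible, ]
  n_el <- table(factor(el$facility_id, levels = fac))
  ev <- tapply(el$outcome, factor(el$facility_id, levels = fac), sum)
  ev[is.na(ev)] <- 0
  by_fac <- data.frame(
    facility_id = fac,
    n_eligible = as.integer(n_el),
    n_events = as.integer(ev),
    stringsAsFactors = FALSE
  )
  by_fac$rate <- ifelse(by_fac$n_eligible > 0,
                        by_fac$n_events / by_fac$n_eligible, NA_real_)
  by_fac$undefined <- by_fac$n_eligible == 0
  by_fac <- by_fac[order(by_fac$facility_id), ]
  rownames(by_fac) <- NULL
  structure(list(
    indicator = indicator,
    by_facility = by_fac,
    prevalence_mean = mean(by_fac$rate, na.rm = TRUE),
    prevalence_sd = sd(by_fac$rate, na.rm = TRUE),
    pooled_rate = sum(by_fac$n_events) / sum(by_fac$n_eligible)
  ), class = "facility_rates")
}

#' @export
print.facility_rates <- function(x, ...) {
  cat(sprintf(
    "facility rates%s: %d facilities | prevalence mean %.1f%% (SD %.1f) | pooled %.1f%%\n",
    if (is.na(x$indicator)) "" else paste0(" [", x$indicator, "]"),
    nrow(x$by_facility), 100 * x$prevalence_mean, 100 * x$prevalence_sd,
    100 * x$pooled_rate))
  invisible(x)
}

#' Exclusion audit: counts per reason
#'
#' @param extracts One extract table or a named list of them.
#' @return Named list (per indicator) of reason -> count tables, suitable for
#'   JSON serialisation.
#' @export
exclusion_audit <- function(extracts) {
  if (is.data.frame(extracts)) extracts <- list(extracts)
  lapply(extracts, function(e) as.list(table(e$exclusion_reason)))
}
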