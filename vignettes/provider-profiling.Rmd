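---
title: "Profiling long-term-care providers: variability, reliability and rankability of quality indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling long-term-care providers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qiprofile)
```

## The problem

Nursing-home quality indicators — the percentage of residents with
polypharmacy, pain, physical restraints or weight loss — are used to
benchmark facilities and are increasingly reported publicly. A facility's
observed rate mixes three things: its true care quality, its case mix, and
sampling noise. Before an indicator is used for benchmarking, two questions
must be answered: does it vary between providers beyond chance
(*between-provider variability*), and does it measure a facility's level
consistently (*reliability*)? `qiprofile` operationalises the standard
answers for binary resident-level outcomes: the latent-scale intraclass
correlation (ICC1), empirical-Bayes caterpillar profiles, rankability, and
the group-mean reliability (ICC2).

## Indicators

Six indicators are built from raw assessment items, each as a
numerator/denominator with exclusion rules applied before the numerator is
evaluated:

| id | numerator | denominator exclusions |
|---|---|---|
| `polypharmacy` | 9 or more active ingredients in the last 7 days | none |
| `pain_self` | daily moderate-or-higher, or nondaily very strong/unbearable self-reported pain | invalid frequency or intensity answer |
| `pain_observed` | same predicate on observed pain | none |
| `restraint_trunk` | daily trunk fixation or seating preventing rising | resident capable of judgment requested/agreed |
| `restraint_bedrails` | daily bedrails on all open sides | resident capable of judgment requested/agreed |
| `weight_loss` | ≥ 5% in 30 days or ≥ 10% in 180 days | life expectancy judged < 6 months; admission assessment |

Residents with missing required items are removed listwise per indicator,
so the per-resident partition *eligible + excluded + listwise-deleted =
total* always holds (a tested invariant). Two literal-reading choices are
deliberate and configurable: restraint cases whose consent context is *not
yet clarified* stay in the denominator (only an affirmative agreement
excludes; set `exclude_unclarified_context = TRUE` for the stricter
variant), and a life-expectancy item recorded as *not collected* does not
exclude. The pain intensity scale is ordered none < mild < moderate <
strong < very strong/unbearable, and "moderate or higher" means the top
three levels.

Facility rates are reported two ways: the unweighted mean (and SD) of
facility rates — the headline figure — and the resident-pooled rate. With
near-equal facility sizes they coincide; with unequal sizes they answer
different questions (the facility is the unit of benchmarking, hence the
headline choice).

## Model and metrics

For indicator-eligible residents, the outcome of resident $i$ in facility
$j$ follows a risk-adjusted random-intercept logistic model

$$\operatorname{logit} P(y_{ij}=1) = \mathbf{x}_{ij}'\boldsymbol\beta + u_j,
\qquad u_j \sim N(0, V_G).$$

Risk adjusters are fixed per indicator: cognitive performance (CPS, 0–6,
numeric) and care level (1–12, numeric) for all six; age additionally for
polypharmacy; depression and gender additionally for both pain indicators.
Coding: age enters in decades centred at 85 years; depression is the
indicator DRS ≥ 3 (the clinical cut for evidence of at least minor
depression); gender is a female indicator. The scores enter as numeric
trends rather than factor levels — a parsimony choice that keeps the
fixed-effects facility model estimable in small facilities.

On the latent logistic scale the residual variance is the constant
$\pi^2/3$, so

$$\mathrm{ICC1} = \frac{V_G}{V_G + \pi^2/3}, \qquad
\mathrm{ICC2} = \frac{V_G}{V_G + (\pi^2/3)/k},$$

with $k$ the number of facilities in the fitted data. ICC2 is the
Spearman–Brown step-up of ICC1 by $k$ and is monotone in both $V_G$ and
$k$; it reduces to ICC1 at $k=1$. Because ICC2 depends on $k$, reliability
figures are only reproducible together with the facility count actually
fitted; the report therefore always carries `k`. An ICC1 above 0.05 is
flagged as relevant between-provider variability (`icc1_relevant`).

*Rankability* contrasts the random-model variance with the sampling noise
of individual facility estimates:
$$\rho = \frac{V_G}{V_G + \operatorname{median}(s_j^2)},$$
where $s_j$ is the standard error of facility $j$'s effect in a parallel
**fixed-effects** logistic model — the same risk adjusters plus sum-to-zero
facility contrasts, so each effect is a deviation from the mean facility.
$\rho$ is classed low (< 0.50), moderate (0.50–0.75) or high (> 0.75).
Facilities whose outcome is constant (zero or all events) have no finite
maximum-likelihood effect; their rows are removed from the fixed-effects
fit (keeping them degrades every facility's standard error through the
sum-to-zero constraint) and they are excluded from the median with their
count logged (`n_nonestimable`). The median makes $\rho$ robust to the
remaining extreme standard errors. The rankability model uses the
risk-adjusted fixed-effects fit; an unadjusted variant is available by
passing `adjusters = character(0)` to `model_spec()`.

## Estimation

The marginal likelihood integrates the facility intercept out per facility.
This is done by adaptive Gauss–Hermite quadrature: for each facility the
integrand's mode is found by damped Newton iterations (the log-posterior is
strictly concave), the quadrature grid is recentred at the mode and scaled
by the curvature there, and the log-integral is accumulated with
log-sum-exp. The outer optimisation runs L-BFGS-B over
$(\boldsymbol\beta, \log V_G)$ — the log parameterisation keeps $V_G \ge 0$
without constraints. Numerical choices:

* quadrature order 15 by default (minimum 7 recommended); on test fixtures
  the log-likelihood changes by < 1e-6 between orders 15 and 31, and the
  order-15 value agrees with dense brute-force trapezoid integration over
  ±8 latent SD to < 1e-6;
* convergence is L-BFGS-B's relative-improvement criterion
  (`factr = 1e7`, ~1e-9 relative; tighten via the `factr` argument), with
  a maximum of 200 iterations and the `converged` flag reported — gradients
  are finite-difference, so an absolute gradient criterion tighter than
  ~1e-5 is not meaningful at realistic sample sizes;
* a fitted $\log V_G$ at the lower box bound (variance < 1e-6) is reported
  as exactly 0; all-zero or all-one outcomes raise a degenerate-data error
  rather than a silent boundary fit;
* at $V_G = 0$ the evaluator returns the exact ordinary logistic-regression
  log-likelihood (model nesting, also a test).

Empirical-Bayes facility effects are the per-facility posterior modes at
the maximum-likelihood estimates, with conditional SDs from the curvature
at the mode; 95% intervals are mode ± 1.96·SD. A normal conditional-SD
interval (rather than a simulation-based one) is the package's choice and
is what the caterpillar display uses. Caterpillar data are centred on the
grand mean of the EB estimates, ordered by estimate (ties broken by
facility id), and classified `below_mean` / `at_mean` / `above_mean` by
whether the interval clears zero — with no multiplicity correction, which
matches the display's conventional use; under a null simulation
($V_G = 0$, 152 facilities) fewer than 7% of facilities are flagged. The
caterpillar x-axis is the logit scale (the native scale of the EB
estimates); probability-scale displays would require a case-mix reference.

Confidence intervals for ICC1/ICC2 use a parametric bootstrap: new facility
effects from $N(0, \hat V_G)$, outcomes from the fitted linear predictor,
refit (warm-started at the parent estimates), percentile 2.5/97.5 interval.
More than 20% failed refits aborts with diagnostics. ICC2 intervals reuse
the same bootstrap draws of $V_G$ (ICC2 is a monotone transform of $V_G$
at fixed $k$).

## The synthetic population

The study data this pipeline is designed for are protected resident
records, so the package generates its own. Two generators share one
configuration (`sim_config()`), a single root seed and per-stream derived
seeds (facility effects, covariates, outcomes, items, consent, exclusions,
missingness), so adding a stream never shifts the others and identical
configurations are byte-identical on disk.

`simulate_outcomes()` draws directly from the random-intercept model —
the tool for metric-recovery studies, with the true facility effect
attached per row. `simulate_items()` generates the full raw-item schema:
each indicator's latent event follows its own random-intercept logistic
model, whose intercept is calibrated numerically (Gauss–Hermite over the
facility effect, averaged over the realised case mix) so the marginal
prevalence lands on the configured target; the latent event is then
translated into items (ingredient counts, pain frequency × intensity
combinations, restraint flags with consent contexts, weight-loss flags).

Defaults emulate the study conditions: 152 facilities × 75 residents
(≈ 11,400); age normal(86.1, 8.36) truncated to [65, 110]; 72.8% female;
care level 1–12 with median 6 (IQR ≈ 4–9); prevalence targets 43.0%
(polypharmacy), 19.7% / 14.9% (self-reported / observed pain), 3.4% / 13.0%
(trunk / bedrail restraint), 7.9% (weight loss); per-indicator facility
SDs implying ICC1s of 0.068 / 0.134 / 0.223 / 0.396 / 0.371 / 0.137; and
13.4% invalid self-reported-pain answers (plus small missingness rates of
0.7% / 1.6% / 0.1% for observed pain, bedrails and weight loss). Where only
means/medians were available, distribution shapes (CPS, DRS, stay length,
the pain frequency × intensity joint distribution, consent rates ~2–4%,
admission-assessment 5%, life-expectancy mix, mild case-mix coefficients
|β| ≤ 0.35) are the package's own assumptions, stated in
`qiprofile:::default_indicator_params()` and configurable.

What the generator does **not** emulate: longitudinal repeated assessments,
instrument-specific export formats, facility-size correlation with quality,
informative missingness, and within-resident correlation across indicators
beyond shared case mix. Passing tests therefore demonstrate that the
estimators recover known truths under the model's assumptions — not that
real assessment data satisfy those assumptions.

## Validation sizes

The shipped suite validates: parameter recovery at 152 × 75 (mean estimated
ICC1 over 20 replicates within ±0.03 of truth at ICC1 ∈ {0.05, 0.15,
0.40}); bootstrap coverage at 50 facilities × 30 residents, intercept-only,
200 bootstrap replicates, 100 simulation replicates (coverage within
[0.88, 0.99]); rankability saturation at facility sizes 25 → 400; and the
null caterpillar calibration at 152 facilities. These sizes are the
package's validation design; larger designs behave the same way and can be
re-run by editing the test parameters.

## Interfaces

Everything is driven from R: `sim_config()` / `read_sim_config()` (YAML),
`simulate_items()` / `simulate_outcomes()`, `extract_indicator()` /
`facility_rates()`, `fit_random_intercept_logistic()` /
`fit_fixed_effects_logistic()` / `empirical_bayes_effects()`, `icc1()` /
`icc2()` / `rankability()` / `bootstrap_ci()` / `variability_report()`,
`build_caterpillar()` / `render_caterpillar()`, and `run_pipeline()`, which
chains all stages and writes the report bundle (CSV + JSON + figure).
`scripts/acceptance.R` is a worked command-line entry point over these
functions; no separate shell CLI is shipped, as the package's users work in
R.

## Known limitations

* A single random intercept per facility: no crossed or nested structures,
  no non-logit links.
* ICC2's strong dependence on $k$ makes it insensitive as a screening
  statistic when $k$ is large — at $k = 152$ even an ICC1 of 0.068 yields
  ICC2 > 0.9. Rankability gives the more nuanced picture; the two are
  strongly concordant across variance grids (a tested property).
* Percentile bootstrap intervals for variance-component functionals can
  slightly undercover near the $V_G = 0$ boundary.
* The fixed-effects model drops constant-outcome facilities; for very
  low-prevalence indicators in small facilities this can remove a
  substantial minority of facilities from the median($s^2$) (the count is
  always reported).
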