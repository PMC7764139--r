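#' Caterpillar-plot data from empirical-Bayes facility effects
#'
#' Centres the facility effects on their grand mean (zero line), orders
#' facilities by estimate (ties broken by facility id) and classifies each
#' facility by whether its 95% interval clears the mean: `below_mean` when the
#' upper bound is negative, `above_mean` when the lower bound is positive,
#' `at_mean` otherwise.
#'
#' @param effects Data frame from [empirical_bayes_effects()].
#' @param indicator Optional indicator id carried into the output.
#' @return Data frame with `facility_id`, `estimate`, `conf_low`,
#'   `conf_high`, `significance`, `rank` (and `indicator` if given), sorted
#'   by estimate.
#' @export
build_caterpillar <- function(effects, indicator = NULL) {
  stopifnot(nrow(effects) >= 1)
  centre <- mean(effects$eb_estimate)
  out <- data.frame(
    facility_id = effects$facility_id,
    estimate = effects$eb_estimate - centre,
    conf_low = effects$conf_low - centre,
    conf_high = effects$conf_high - centre,
    stringsAsFactors = FALSE
  )
  out$significance <- ifelse(out$conf_high < 0, "below_mean",
                             ifelse(out$conf_low > 0, "above_mean",
                                    "at_mean"))
  out <- out[order(out$estimate, out$facility_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(indicator)) out <- cbind(indicator = indicator, out,
                                        stringsAsFactors = FALSE)
  out
}

#' Render caterpillar plots
#'
#' One panel per indicator (if an `indicator` column is present): a horizontal
#' whisker per facility on the logit scale, facilities ordered by estimate on
#' the vertical axis, and a vertical line at the grand mean (zero). Facilities
#' whose whisker clears the line differ significantly from the mean.
#'
#' @param data Output of [build_caterpillar()] (rows from several indicators
#'   may be stacked).
#' @param path Output file (`.png` or `.pdf`).
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
render_caterpillar <- function(data, path, width = 9, height = 6, dpi = 150) {
  if (is.null(data) || !nrow(data)) {
    p <- ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0, label = "no eligible data") +
      ggplot2::theme_void()
  } else {
    p <- ggplot2::ggplot(
      data, ggplot2::aes(x = estimate, y = rank)) +
      ggplot2::geom_vline(xintercept = 0, linewidth = 0.3,
                          colour = "grey30") +
      ggplot2::geom_segment(
        ggplot2::aes(x = conf_low, xend = conf_high,
                     yend = rank, colour = significance),
        linewidth = 0.3) +
      ggplot2::geom_point(size = 0.5) +
      ggplot2::scale_colour_manual(values = c(
        below_mean = "#2166ac", at_mean = "grey60", above_mean = "#b2182b"),
        drop = FALSE) +
      ggplot2::labs(x = "facility effect (logit scale, centred)",
                    y = "facility (ordered by estimate)") +
      ggplot2::theme_minimal(base_size = 9)
    if ("indicator" %in% names(data))
      p <- p + ggplot2::facet_wrap(~indicator, scales = "free")
  }
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}

#' Run the full profiling pipeline
#'
#' Chains simulate (or load) -> indicator extraction -> random-intercept and
#' fixed-effects fits -> variability/reliability metrics -> caterpillar data,
#' for a set of indicators, and optionally writes the report bundle
#' (delimited text + JSON + figure) to a directory. Any indicator-level
#' failure is rethrown with the indicator id in the message.
#'
#' @param sim A [sim_config()]; ignored when `records` is supplied.
#' @param records Optional resident table (e.g. from [read_residents()]).
#' @param indicators Indicator subset to process.
#' @param quad_order Quadrature order for the random-intercept fits.
#' @param n_boot Bootstrap replicates for ICC confidence intervals (0 = skip).
#' @param outdir Optional output directory; created if needed.
#' @param make_plots Whether to render the caterpillar figure (requires
#'   `outdir`).
#' @return List with `records`, `extracts`, `rates`, `fits`, `effects`,
#'   `report` (one row per indicator), `caterpillar`, `audit`.
#' @export
run_pipeline <- function(sim = sim_config(), records = NULL,
                         indicators = indicator_ids(), quad_order = 15,
                         n_boot = 0, outdir = NULL,
                         make_plots = !is.null(outdir)) {
  indicators <- match.arg(indicators, indicator_ids(), several.ok = TRUE)
  if (is.null(records)) records <- simulate_items(sim)
  validate_residents(records)
  cov <- encode_adjusters(records, sim$covariate_params$export_date)
  covcols <- c("resident_id", coded_covariate_names())

  extracts <- list(); rates <- list(); fits <- list()
  effects <- list(); cater <- list(); report <- list()
  for (i in seq_along(indicators)) {
    id <- indicators[i]
    step <- function(expr) {
      tryCatch(expr, error = function(e)
        stop(sprintf("[%s] %s", id, conditionMessage(e)), call. = FALSE))
    }
    ex <- step(extract_indicator(records, id))
    extracts[[id]] <- ex
    rates[[id]] <- step(facility_rates(ex, id))
    md <- merge(ex[ex$eligible, c("facility_id", "resident_id", "outcome")],
                cov[covcols], by = "resident_id")
    spec <- model_spec(id)
    fit <- step(fit_random_intercept_logistic(md, spec,
                                              quad_order = quad_order))
    fits[[id]] <- fit
    fe <- step(fit_fixed_effects_logistic(md, spec))
    eb <- step(empirical_bayes_effects(fit))
    effects[[id]] <- facility_effects(eb, fe)
    report[[id]] <- step(variability_report(
      fit, fe, n_boot = n_boot,
      seed = (sim$seed %% 100000L) * 17L + i))
    cater[[id]] <- build_caterpillar(eb, indicator = id)
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  cater <- do.call(rbind, cater)
  rownames(cater) <- NULL
  audit <- exclusion_audit(extracts)

  bundle <- list(records = records, extracts = extracts, rates = rates,
                 fits = fits, effects = effects, report = report,
                 caterpillar = cater, audit = audit)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_residents(records, file.path(outdir, "residents.csv"))
    fr <- do.call(rbind, lapply(names(rates), function(id)
      cbind(indicator = id, rates[[id]]$by_facility)))
    write.csv(fr, file.path(outdir, "facility_rates.csv"), row.names = FALSE)
    write.csv(report, file.path(outdir, "variability_report.csv"),
              row.names = FALSE)
    write.csv(cater, file.path(outdir, "caterpillar.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(report = report, audit = audit),
      file.path(outdir, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = 10, pretty = TRUE)
    if (make_plots)
      render_caterpillar(cater, file.path(outdir, "caterpillar.png"))
  }
  invisible(bundle)
}
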