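#' Prediction instability plot
#'
#' Each individual's true risk (x-axis) against their risk-scale
#' uncertainty interval (vertical segment), with the identity line and two
#' locally weighted (lowess, span 0.3) smoother curves fitted separately
#' through the upper and lower interval bounds. The smoothers describe a
#' "typical" interval at each risk level across the whole risk spectrum.
#' Axes are fixed to the unit square. Deterministic given the records.
#'
#' @param profile A [precision_profile()].
#' @param span Lowess smoother span (default 0.3).
#' @param segment_col,smoother_col Colours for intervals and smoothers.
#' @param ... Passed to [graphics::plot()].
#' @return The profile, invisibly. Warns (and omits the smoothers) with
#'   fewer than 10 records.
#' @export
prediction_instability_plot <- function(profile, span = 0.3,
                                        segment_col = "grey60",
                                        smoother_col = "blue", ...) {
  stopifnot(inherits(profile, "precision_profile"))
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "true event risk",
                 ylab = sprintf("%g%% uncertainty interval",
                                100 * attr(profile, "level")),
                 main = sprintf("Prediction instability (n = %g)",
                                attr(profile, "n")), ...)
  graphics::segments(profile$risk, profile$lower, profile$risk,
                     profile$upper, col = segment_col)
  graphics::abline(0, 1, lty = 2)
  if (nrow(profile) >= 10) {
    o <- order(profile$risk)
    graphics::lines(stats::lowess(profile$risk[o], profile$lower[o],
                                  f = span), col = smoother_col, lwd = 2)
    graphics::lines(stats::lowess(profile$risk[o], profile$upper[o],
                                  f = span), col = smoother_col, lwd = 2)
  } else {
    warning("fewer than 10 records: smoother curves omitted")
  }
  invisible(profile)
}

#' Classification instability plot
#'
#' Each individual's true risk (x-axis) against the probability that their
#' uncertainty distribution falls on the opposite side of the clinical risk
#' threshold (y-axis), with a vertical line at the threshold. Under the
#' analytic (normal) mode the probability is at most 0.5, approached as the
#' true risk nears the threshold.
#'
#' @param profile A [precision_profile()].
#' @param threshold Clinical risk threshold in (0, 1).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the vector of misclassification probabilities.
#' @export
classification_instability_plot <- function(profile, threshold, ...) {
  stopifnot(inherits(profile, "precision_profile"))
  p <- misclassification_probability(profile$mu, profile$var_mu, threshold,
                                     attr(profile, "t"))
  graphics::plot(profile$risk, p, xlim = c(0, 1), ylim = c(0, 0.5),
                 xlab = "true event risk",
                 ylab = "P(opposite side of threshold)",
                 main = sprintf("Classification instability (n = %g, threshold = %g)",
                                attr(profile, "n"), threshold), ...)
  graphics::abline(v = threshold, lty = 2)
  invisible(p)
}

#' End-to-end precision assessment for candidate sample sizes
#'
#' Runs the full design-stage pipeline for one or more candidate
#' development sample sizes: score the cohort under the core model, build
#' the unit information matrix (simulating follow-up first if the cohort
#' has none), derive per-individual precision profiles at each candidate
#' n, and summarise interval widths, MAPE/RMSPE and misclassification —
#' overall, by subgroup and by true-risk stratum. Optionally writes the
#' per-n profile CSVs, summary tables (CSV + JSON) and a manifest to an
#' output directory, and instability plots as PNGs.
#'
#' @param cohort A [cohort()]; follow-up is simulated from `scheme` when
#'   absent.
#' @param model A [core_model()].
#' @param n_candidates Vector of candidate sample sizes.
#' @param threshold Clinical risk threshold.
#' @param scheme A [censoring_scheme()] used only when the cohort lacks
#'   follow-up.
#' @param group Optional subgroup column name for fairness summaries.
#' @param risk_strata Optional true-risk strata upper bounds.
#' @param level Confidence level.
#' @param draws MAPE/RMSPE draws per individual.
#' @param seed Integer seed governing all simulation in the run.
#' @param out_dir Optional output directory.
#' @param plots Write instability plots (requires `out_dir`).
#' @return A list with `info`, `profiles` (one [precision_profile()] per
#'   candidate n), `summaries` (one [summarise_instability()] table per n)
#'   and `manifest`.
#' @export
run_assess <- function(cohort, model, n_candidates, threshold = 0.2,
                       scheme = NULL, group = NULL, risk_strata = NULL,
                       level = 0.95, draws = 1000L, seed = 1L,
                       out_dir = NULL, plots = FALSE) {
  stopifnot(inherits(cohort, "cohort"), inherits(model, "core_model"),
            all(n_candidates > 0))
  if (is.null(cohort$time)) {
    if (is.null(scheme)) {
      stop_stabsize("cohort lacks follow-up: provide a censoring scheme",
                    "state_error")
    }
    cohort <- simulate_followup(cohort, model, scheme, seed)
  }
  info <- unit_information(cohort, model)
  profiles <- list()
  summaries <- list()
  for (n in n_candidates) {
    key <- as.character(n)
    profiles[[key]] <- precision_profile(model, cohort, n, info = info,
                                         level = level)
    summaries[[key]] <- summarise_instability(
      profiles[[key]], threshold = threshold, group = group,
      risk_strata = risk_strata, draws = draws, seed = seed)
  }
  manifest <- list(
    n_candidates = n_candidates, threshold = threshold, level = level,
    draws = draws, seed = seed, horizon = model$horizon,
    alpha = model$alpha, delta = model$delta,
    weights = as.list(model$weights),
    cohort_n = nrow(cohort$predictors),
    information_condition = info$condition
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(profiles)) {
      utils::write.csv(as.data.frame(profiles[[key]]),
                       file.path(out_dir, sprintf("profile_n%s.csv", key)),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(summaries[[key]]),
                       file.path(out_dir, sprintf("summary_n%s.csv", key)),
                       row.names = FALSE)
      if (plots) {
        grDevices::png(file.path(out_dir, sprintf("instability_n%s.png", key)),
                       width = 1400, height = 700, res = 120)
        graphics::par(mfrow = c(1, 2))
        prediction_instability_plot(profiles[[key]])
        classification_instability_plot(profiles[[key]], threshold)
        grDevices::dev.off()
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(info = info, profiles = profiles, summaries = summaries,
       manifest = manifest)
}

#' End-to-end required sample size report
#'
#' Applies the required-n inversion over the cohort for a band
#' specification or a single width target (optionally restricted to a
#' subset, e.g. low-risk individuals), and reports the per-individual n
#' distribution plus the overall recommendation.
#'
#' @param cohort A [cohort()] (with follow-up, or provide `scheme`).
#' @param model A [core_model()].
#' @param spec A [sample_size_spec()], or `NULL` with `target_width`.
#' @param target_width Single width target used when `spec` is `NULL`.
#' @param subset Optional logical mask over individuals.
#' @param scheme Censoring scheme if follow-up must be simulated.
#' @param level Confidence level.
#' @param seed Seed for follow-up simulation.
#' @param out_dir Optional output directory (JSON report + CSV).
#' @return The [cohort_required_n()] result plus the information matrix.
#' @export
run_size <- function(cohort, model, spec = NULL, target_width = NULL,
                     subset = NULL, scheme = NULL, level = 0.95, seed = 1L,
                     out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(model, "core_model"))
  if (is.null(cohort$time)) {
    if (is.null(scheme)) {
      stop_stabsize("cohort lacks follow-up: provide a censoring scheme",
                    "state_error")
    }
    cohort <- simulate_followup(cohort, model, scheme, seed)
  }
  info <- unit_information(cohort, model)
  res <- cohort_required_n(info, cohort, model, spec = spec,
                           target_width = target_width, subset = subset,
                           level = level)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$per_individual,
                     file.path(out_dir, "required_n_per_individual.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(overall_n = res$overall_n,
           n_targeted = nrow(res$per_individual),
           n_quartiles = as.list(stats::quantile(res$per_individual$n_raw,
                                                 c(0.25, 0.5, 0.75)))),
      file.path(out_dir, "required_n.json"), auto_unbox = TRUE, digits = NA)
  }
  c(res, list(info = info))
}
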