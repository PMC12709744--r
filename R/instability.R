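#' Probability of misclassification against a risk threshold
#'
#' The mass of an individual's risk uncertainty distribution falling on the
#' opposite side of a clinical risk threshold from their true risk. In the
#' analytic mode the threshold \eqn{p^*} is mapped to the log-rate scale,
#' \eqn{\mu^* = \ln(-\ln(1 - p^*)/t)}, where the uncertainty distribution
#' is normal, giving \eqn{\Phi(-|\mu - \mu^*| / \sqrt{\mathrm{var}(\hat\mu)})}
#' exactly. The Monte-Carlo mode computes the fraction of sampled risks on
#' the opposite side and converges to the analytic value.
#'
#' An individual whose true risk sits exactly at the threshold is assigned
#' probability 0.5 (the symmetric limit); with zero variance and true risk
#' away from the threshold the probability is 0.
#'
#' @param mu True linear predictor(s).
#' @param var_mu Variance(s) of \eqn{\hat\mu} (>= 0).
#' @param threshold Clinical risk threshold \eqn{p^*} in (0, 1).
#' @param t Horizon in years.
#' @param method `"analytic"` (default, exact and deterministic) or `"mc"`.
#' @param draws,seed Monte-Carlo settings.
#' @return Misclassification probability(ies) in [0, 0.5].
#' @export
#' @examples
#' misclassification_probability(-2.3139, 0.04, threshold = 0.20, t = 5)
misclassification_probability <- function(mu, var_mu, threshold, t,
                                          method = c("analytic", "mc"),
                                          draws = 1000L, seed = 1L) {
  stopifnot(threshold > 0, threshold < 1, all(var_mu >= 0))
  method <- match.arg(method)
  mu_star <- risk_to_mu(threshold, t)
  if (method == "analytic") {
    s <- sqrt(var_mu)
    out <- ifelse(s == 0,
                  ifelse(mu == mu_star, 0.5, 0),
                  stats::pnorm(-abs(mu - mu_star) / s))
    return(unname(out))
  }
  risk_true <- event_risk(mu, t)
  vapply(seq_along(mu), function(i) {
    if (var_mu[i] == 0) {
      return(if (mu[i] == mu_star) 0.5 else 0)
    }
    r <- sample_uncertainty_distribution(mu[i], var_mu[i], t, draws,
                                         seed + i - 1L)
    if (risk_true[i] >= threshold) mean(r < threshold) else mean(r > threshold)
  }, numeric(1))
}

#' Mean absolute / root-mean-squared prediction error
#'
#' Summarises the spread of an individual's risk uncertainty distribution
#' around their true risk: `mape` is the mean absolute difference between
#' sampled risks and the true risk over seeded draws; `rmspe` is the root
#' of the mean squared difference. Both are vectorised over individuals.
#'
#' @param mu True linear predictor(s).
#' @param var_mu Variance(s) of \eqn{\hat\mu}.
#' @param t Horizon in years.
#' @param draws Draws per individual (default 1000).
#' @param seed Integer seed (individual i uses `seed + i - 1`).
#' @return Numeric vector of errors on the risk scale.
#' @export
mape <- function(mu, var_mu, t, draws = 1000L, seed = 1L) {
  prediction_error(mu, var_mu, t, draws, seed, squared = FALSE)
}

#' @rdname mape
#' @export
rmspe <- function(mu, var_mu, t, draws = 1000L, seed = 1L) {
  prediction_error(mu, var_mu, t, draws, seed, squared = TRUE)
}

prediction_error <- function(mu, var_mu, t, draws, seed, squared) {
  stopifnot(length(mu) == length(var_mu), all(var_mu >= 0), draws >= 1)
  risk_true <- event_risk(mu, t)
  vapply(seq_along(mu), function(i) {
    r <- sample_uncertainty_distribution(mu[i], var_mu[i], t, draws,
                                         seed + i - 1L)
    d <- r - risk_true[i]
    if (squared) sqrt(mean(d^2)) else mean(abs(d))
  }, numeric(1))
}

#' Instability summary tables, overall and by subgroup
#'
#' For a precision profile at a candidate sample size, computes each
#' individual's interval width, MAPE, RMSPE and misclassification
#' probability, then reports mean (min, median, max) of each statistic —
#' overall, within each level of an optional subgroup label (the
#' design-stage fairness check), and within optional true-risk strata.
#'
#' @param profile A [precision_profile()].
#' @param threshold Clinical risk threshold for misclassification.
#' @param group Name of a subgroup column carried by the profile's cohort,
#'   or a vector of labels; `NULL` for overall only.
#' @param risk_strata Optional upper bounds of true-risk strata (e.g.
#'   `c(0.3)` adds a "risk<=0.3" row).
#' @param draws,seed Settings for the sampling-based MAPE/RMSPE.
#' @return An `instability_summary` data frame: one row per group with
#'   columns `<stat>_<mean|min|median|max>` for each of width, mape,
#'   rmspe, misclassification.
#' @export
summarise_instability <- function(profile, threshold, group = NULL,
                                  risk_strata = NULL, draws = 1000L,
                                  seed = 1L) {
  stopifnot(inherits(profile, "precision_profile"))
  t <- attr(profile, "t")
  metrics <- data.frame(
    width = profile$width,
    mape = mape(profile$mu, profile$var_mu, t, draws, seed),
    rmspe = rmspe(profile$mu, profile$var_mu, t, draws, seed),
    misclassification = misclassification_probability(
      profile$mu, profile$var_mu, threshold, t)
  )
  one_row <- function(label, idx) {
    stats_ <- lapply(metrics[idx, , drop = FALSE], four_num)
    row <- data.frame(group = label, n_individuals = sum(idx))
    for (nm in names(stats_)) {
      v <- stats_[[nm]]
      row[paste0(nm, "_", c("mean", "min", "median", "max"))] <-
        as.list(unname(v))
    }
    row
  }
  all_idx <- rep(TRUE, nrow(profile))
  out <- one_row("all", all_idx)
  if (!is.null(group)) {
    if (is.character(group) && length(group) == 1L) {
      sg <- attr(profile, "subgroups")
      if (is.null(sg) || !group %in% names(sg)) {
        stop_stabsize(sprintf("unknown subgroup column '%s'", group),
                      "schema_error")
      }
      labels <- sg[[group]]
    } else {
      labels <- group
      stopifnot(length(labels) == nrow(profile))
    }
    for (l in sort(unique(labels))) {
      out <- rbind(out, one_row(l, labels == l))
    }
  }
  for (ub in risk_strata) {
    out <- rbind(out, one_row(sprintf("risk<=%g", ub), profile$risk <= ub))
  }
  attr(out, "threshold") <- threshold
  attr(out, "n") <- attr(profile, "n")
  class(out) <- c("instability_summary", "data.frame")
  out
}

#' @export
print.instability_summary <- function(x, digits = 3, ...) {
  cat(sprintf("<instability summary> n = %g, threshold = %g\n",
              attr(x, "n"), attr(x, "threshold")))
  fmt <- function(stub) {
    sprintf("%.*g (%.*g, %.*g, %.*g)",
            digits, x[[paste0(stub, "_mean")]],
            digits, x[[paste0(stub, "_min")]],
            digits, x[[paste0(stub, "_median")]],
            digits, x[[paste0(stub, "_max")]])
  }
  tab <- data.frame(group = x$group, n = x$n_individuals,
                    width = fmt("width"), MAPE = fmt("mape"),
                    misclassification = fmt("misclassification"))
  print(tab, row.names = FALSE)
  invisible(x)
}
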