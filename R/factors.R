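#' Univariate logistic regression of an outcome on a hospital characteristic
#'
#' Patient-level logistic regression of 30-day death (or 2-year alive)
#' status on a hospital-level covariate replicated to patients. Accepts
#' either patient records (outcome derived via [observable_at()]) or a
#' binomial-aggregated per-hospital table (`events`, `n`, covariate value) —
#' the two representations give identical maximum-likelihood fits, which is
#' asserted by the test suite.
#'
#' Case volume enters as the natural log of the number of patients; by
#' default the complete-case count, the definition consistent with the
#' emulated registry's published fit (`volume_definition = "complete"`),
#' with `"total"` (all registered patients) available.
#'
#' @param data Either a `registry` with an attached hospital table, or an
#'   aggregate data frame with columns `events`, `n` and the covariate.
#' @param outcome "early_death" or "late_survival".
#' @param covariate "log_volume", "academic" or "biopsy_fraction" (for
#'   aggregate input, any column name present in `data`).
#' @param hospital_data Per-hospital data frame (`hospital_id` plus
#'   `volume`/`academic`/`biopsy_fraction`) required for record input.
#' @param transform Applied to the covariate: "log" (default for volume) or
#'   "identity".
#' @return A `logistic_fit`: coefficients, SEs, Wald p, n, events, covariate
#'   bookkeeping, separation flag.
#' @export
patient_level_logistic <- function(data, outcome = c("early_death", "late_survival"),
                                   covariate = "log_volume",
                                   hospital_data = NULL,
                                   transform = NULL) {
  outcome <- match.arg(outcome)
  if (inherits(data, "registry")) {
    stopifnot(!is.null(hospital_data))
    horizon <- if (outcome == "early_death") 30 else 730
    obs <- observable_at(data, horizon)
    ev <- if (outcome == "early_death") obs$dead_by_horizon else !obs$dead_by_horizon
    agg <- data.frame(
      hospital_id = sort(unique(obs$hospital_id)),
      events = as.integer(rowsum(as.integer(ev), obs$hospital_id)),
      n = as.integer(table(factor(obs$hospital_id,
                                  levels = sort(unique(obs$hospital_id)))))
    )
    agg <- merge(agg, hospital_data, by = "hospital_id")
    data <- agg
  }
  stopifnot(all(c("events", "n") %in% names(data)))
  raw_name <- switch(covariate, log_volume = "volume", covariate)
  if (!raw_name %in% names(data)) stop("covariate column not found: ", raw_name)
  x_raw <- as.numeric(data[[raw_name]])
  transform <- transform %||% if (covariate == "log_volume") "log" else "identity"
  x <- if (transform == "log") log(x_raw) else x_raw
  if (diff(range(x)) == 0) stop("zero-variance covariate: ", covariate)

  fit <- suppressWarnings(
    glm(cbind(events, n - events) ~ x, family = binomial(), data = data,
        control = list(epsilon = 1e-12, maxit = 50))
  )
  sep <- !fit$converged || any(abs(coef(fit)) > 15)
  est <- coef(fit); se <- sqrt(diag(vcov(fit)))
  out <- list(
    intercept = unname(est[1]), slope = unname(est[2]),
    se_intercept = unname(se[1]), se_slope = unname(se[2]),
    p = unname(2 * pnorm(-abs(est[2] / se[2]))),
    covariate = covariate, transform = transform,
    n = sum(data$n), events = sum(data$events),
    pooled_rate = sum(data$events) / sum(data$n),
    separation = sep, table = data
  )
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: %s (%s), n = %d, events = %d\n",
              x$covariate, x$transform, x$n, x$events))
  cat(sprintf("  log OR = %.3f (SE %.3f), P = %.4g%s\n", x$slope, x$se_slope,
              x$p, if (x$separation) "  [separation flagged]" else ""))
  invisible(x)
}

#' Volume at which the fitted mortality curve crosses a reference rate
#'
#' Solves `intercept + slope * log(v) = logit(rate)` for `v`: the boundary
#' between higher- and lower-than-average event rates on the fitted
#' log-volume logistic curve. The reference defaults to the pooled observed
#' event rate of the fit.
#'
#' @param fit A `logistic_fit` with a log-volume covariate.
#' @param reference_rate Probability defining the boundary.
#' @return Volume in patients (over the registry period).
#' @export
boundary_volume <- function(fit, reference_rate = fit$pooled_rate) {
  stopifnot(inherits(fit, "logistic_fit"), fit$transform == "log")
  if (fit$slope == 0) stop("slope is zero: the fitted curve never crosses the reference rate")
  exp((qlogis(reference_rate) - fit$intercept) / fit$slope)
}

#' Relative odds change for a relative volume increase
#'
#' For a log-volume slope b and a volume increase of `delta` (e.g. 0.10 for
#' +10%), the exact relative odds change is `exp(b * log(1 + delta)) - 1`;
#' the common small-change approximation is `b * delta`. Both conventions are
#' returned since published summaries differ in which they quote.
#'
#' @param slope Log-odds-ratio per unit of log volume.
#' @param delta Relative volume increase (fraction).
#' @return List with `exact` and `approx` relative odds changes.
#' @export
relative_effect <- function(slope, delta) {
  list(exact = exp(slope * log1p(delta)) - 1, approx = slope * delta)
}

#' Hospital-characteristic exploration on an aggregate table
#'
#' Runs [patient_level_logistic()] on an aggregate hospital table (such as
#' [hospital_aggregates()] without the overall row) for one outcome and one
#' covariate, deriving the binomial columns from the table's count fields.
#'
#' @param tab Aggregate table with `deaths_30d`/`observable_30d`,
#'   `survivors_2y`/`observable_2y`, `n_total`, `n_complete`, `academic`,
#'   `biopsy_pct` columns.
#' @param outcome "early_death" or "late_survival".
#' @param covariate "log_volume", "academic" or "biopsy_fraction".
#' @param volume_definition "complete" (complete-case count, default) or
#'   "total" (all registered patients).
#' @return A `logistic_fit`.
#' @export
explore_hospital_factors <- function(tab, outcome = "early_death",
                                     covariate = "log_volume",
                                     volume_definition = c("complete", "total")) {
  volume_definition <- match.arg(volume_definition)
  tab <- tab[tab$hospital_id != "overall", , drop = FALSE]
  df <- data.frame(
    hospital_id = tab$hospital_id,
    events = if (outcome == "early_death") tab$deaths_30d else tab$survivors_2y,
    n = if (outcome == "early_death") tab$observable_30d else tab$observable_2y,
    volume = if (volume_definition == "complete") tab$n_complete else tab$n_total,
    academic = as.numeric(tab$academic),
    biopsy_fraction = tab$biopsy_pct / 100
  )
  patient_level_logistic(df, outcome, covariate)
}
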