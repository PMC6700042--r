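#' Patient-specific expected survival at the average hospital
#'
#' Per posterior draw, `S(t) = exp(-exp(x beta) * Lambda0(t))` with the
#' hospital random effect set to 0 (a fictitious hospital of average
#' performance). `Lambda0` is the exact piecewise-linear cumulative baseline;
#' times beyond the last finite break use the open-ended final hazard.
#'
#' @param fit A `pe_fit`.
#' @param X Covariate matrix on the model scale (as in the fit), or a
#'   complete-case `registry` (converted via [model_covariates()] with the
#'   fit's scaling).
#' @param t Single time point (days), `t >= 0`.
#' @param u Log-hazard offset added per patient (default 0 = average
#'   hospital; supply e.g. a frailty draw for fitted curves).
#' @return Matrix (patients x draws) of survival probabilities.
#' @export
expected_survival_function <- function(fit, X, t, u = 0) {
  stopifnot(t >= 0)
  X <- .fit_X(fit, X)
  dm <- fit_draws(fit)
  beta <- dm[, paste0("beta_", fit$covariates), drop = FALSE]
  loglam <- dm[, grep("^loglam", colnames(dm)), drop = FALSE]
  K <- ncol(loglam)
  lo <- fit$breaks[-length(fit$breaks)]
  hi <- fit$breaks[-1]
  # per-draw cumulative baseline at t: exact sum of interval overlaps,
  # restricted to overlapping intervals so that data-free intervals beyond t
  # (whose hazard draws are unconstrained) cannot contribute Inf * 0
  overlap <- pmax(0, pmin(t, hi) - lo)
  idx <- which(overlap > 0)
  Lam <- if (length(idx)) drop(exp(loglam[, idx, drop = FALSE]) %*% overlap[idx])
         else numeric(nrow(loglam))
  relrisk <- exp(tcrossprod(X, beta) + rep(u, length.out = nrow(X)))  # n x draws
  exp(-sweep(relrisk, 2, Lam, "*"))
}

.fit_X <- function(fit, X) {
  if (inherits(X, "registry") || (is.data.frame(X) && "age" %in% names(X))) {
    sc <- fit$scaling
    X <- model_covariates(X, age_center = sc$age_center,
                          kps_center = sc$kps_center, ref_year = sc$ref_year)
  }
  X <- as.matrix(X)
  stopifnot(identical(colnames(X), fit$covariates))
  X
}

#' Per-hospital expected event counts under risk standardization
#'
#' For early death the per-patient event probability is `1 - S(30)`; for late
#' survival it is `S(730)`. Probabilities are computed per posterior draw at
#' random effect 0, summed over a hospital's observable patients, and the
#' per-draw sums are summarized by the posterior median (default) or by the
#' plug-in sum of posterior-median patient probabilities.
#'
#' @param fit A `pe_fit`.
#' @param records Complete-case `registry` (restricted internally via
#'   [observable_at()] at the kind's horizon).
#' @param kind "early_death" (30-day) or "late_survival" (730-day).
#' @param summary "median_of_sums" (default) or "plugin".
#' @return Data frame: hospital_id, observed, expected, n_observable.
#' @export
expected_events <- function(fit, records,
                            kind = c("early_death", "late_survival"),
                            summary = c("median_of_sums", "plugin")) {
  kind <- match.arg(kind)
  summary <- match.arg(summary)
  horizon <- if (kind == "early_death") 30 else 730
  obs <- observable_at(records, horizon)
  empty <- setdiff(unique(records$hospital_id), unique(obs$hospital_id))
  if (length(empty)) {
    message("hospitals with no observable patients at ", horizon, "d omitted: ",
            paste(empty, collapse = ", "))
  }
  S <- expected_survival_function(fit, obs, horizon)
  P <- if (kind == "early_death") 1 - S else S
  if (kind == "late_survival") {
    # patients observable only because they died (potential follow-up short
    # of the horizon) can never contribute an observed survivor; conditional
    # on being observable their survival probability is zero, so they must
    # contribute zero expected survivors or the O/E ratio is biased low
    P[obs$potential_followup_days < horizon, ] <- 0
  }
  event_obs <- if (kind == "early_death") obs$dead_by_horizon else !obs$dead_by_horizon
  hosp <- sort(unique(obs$hospital_id))
  if (summary == "median_of_sums") {
    sums <- rowsum(P, obs$hospital_id)                 # hospital x draws
    expected <- apply(sums, 1, median)[hosp]
  } else {
    pmed <- apply(P, 1, median)
    expected <- drop(rowsum(pmed, obs$hospital_id))[hosp]
  }
  data.frame(
    hospital_id = hosp,
    observed = as.integer(rowsum(as.integer(event_obs), obs$hospital_id)[hosp, 1]),
    expected = unname(expected),
    n_observable = as.integer(table(factor(obs$hospital_id, levels = hosp))),
    kind = kind,
    stringsAsFactors = FALSE
  )
}

#' Observed-to-expected ratios
#'
#' `ratio = observed / expected`, exactly; flags are initialized to "within"
#' and filled by [flag_outliers()].
#'
#' @param expected Data frame from [expected_events()] (columns hospital_id,
#'   observed, expected, kind), or separate vectors via `observed`.
#' @param observed Optional observed counts when `expected` is a plain
#'   expected-count vector.
#' @return A `standardized_ratio` data frame.
#' @export
oe_ratios <- function(expected, observed = NULL) {
  if (is.data.frame(expected)) {
    tab <- expected
  } else {
    tab <- data.frame(hospital_id = names(expected) %||% seq_along(expected),
                      observed = observed, expected = as.numeric(expected),
                      kind = NA_character_, stringsAsFactors = FALSE)
  }
  if (any(tab$expected <= 0)) {
    stop("expected count must be positive to form an O/E ratio (hospital ",
         paste(tab$hospital_id[tab$expected <= 0], collapse = ", "), ")")
  }
  tab$ratio <- tab$observed / tab$expected
  tab$flag <- "within"
  tab$direction <- NA_character_
  class(tab) <- c("standardized_ratio", "data.frame")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Risk-standardize both outcomes of a registry
#'
#' Convenience wrapper: expected events and O/E ratios for early death and
#' late survival in one table.
#'
#' @param fit A `pe_fit`.
#' @param records Complete-case `registry`.
#' @param summary Passed to [expected_events()].
#' @return A `standardized_ratio` data frame covering both kinds.
#' @export
standardize <- function(fit, records, summary = "median_of_sums") {
  rbind(
    oe_ratios(expected_events(fit, records, "early_death", summary)),
    oe_ratios(expected_events(fit, records, "late_survival", summary))
  )
}
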