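#' Model covariate matrix on the fitting scale
#'
#' Age enters as (age - center)/10 (hazard ratios are per decade), KPS as
#' (kps - center)/10 (per 10 ladder points), treatment year as indicator
#' columns against the reference year.
#'
#' @param records Complete-case `registry` data frame.
#' @param age_center,kps_center Centering constants (cohort means of the
#'   emulated registry).
#' @param ref_year Reference treatment year.
#' @return Numeric matrix with scaling recorded in attributes.
#' @export
model_covariates <- function(records, age_center = 61.4, kps_center = 80,
                             ref_year = 2011) {
  stopifnot(!anyNA(records$age), !anyNA(records$kps), !anyNA(records$year))
  yrs <- sort(unique(records$year))
  X <- cbind(age = (records$age - age_center) / 10,
             kps = (records$kps - kps_center) / 10)
  for (y in setdiff(yrs, ref_year)) {
    X <- cbind(X, as.numeric(records$year == y))
    colnames(X)[ncol(X)] <- paste0("year", y)
  }
  attr(X, "scaling") <- list(age_center = age_center, kps_center = kps_center,
                             age_scale = 10, kps_scale = 10, ref_year = ref_year)
  X
}

#' Expand records into a counting-process (patient x interval) table
#'
#' One row per patient per baseline interval at risk: the log-Poisson
#' representation of the piecewise-exponential proportional-hazards model.
#' Exposure is the time spent in the interval; the event indicator is 1 only
#' in the row where death occurs. A death recorded at day 0 would give a
#' zero-exposure row, so it is assigned a minimal exposure of half a day
#' (count recorded in attribute `n_zero_adjusted`).
#'
#' @param records Complete-case `registry` data frame.
#' @param breaks Interval breaks; must start at 0, increase strictly, and
#'   contain the 30- and 730-day horizons.
#' @param ... Passed to [model_covariates()].
#' @return A `counting_process` data frame with columns `patient_id`,
#'   `hospital_id`, `interval`, `tstart`, `exposure`, `event` and the
#'   covariate columns; breaks and scaling kept as attributes.
#' @export
build_counting_process <- function(records, breaks = default_breaks(), ...) {
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
  stopifnot(breaks[1] == 0, all(c(30, 730) %in% breaks))
  t <- records$time_days
  dead <- records$status == "dead"
  # interval k covers (breaks[k], breaks[k+1]]; time 0 clamps into interval 1
  m <- pmax(1L, findInterval(t, breaks, left.open = TRUE))
  idx <- rep(seq_along(t), m)
  k <- sequence(m)
  tstart <- breaks[k]
  tstop <- pmin(t[idx], breaks[k + 1])
  exposure <- tstop - tstart
  event <- as.integer(dead[idx] & k == m[idx])
  zero <- exposure <= 0
  n_zero <- sum(zero)
  exposure[zero] <- 0.5

  X <- model_covariates(records, ...)
  cp <- data.frame(
    patient_id = records$patient_id[idx],
    hospital_id = records$hospital_id[idx],
    interval = k, tstart = tstart,
    exposure = exposure, event = event,
    stringsAsFactors = FALSE
  )
  cp <- cbind(cp, X[idx, , drop = FALSE])
  attr(cp, "breaks") <- breaks
  attr(cp, "scaling") <- attr(X, "scaling")
  attr(cp, "covariates") <- colnames(X)
  attr(cp, "n_zero_adjusted") <- n_zero
  class(cp) <- c("counting_process", "data.frame")
  cp
}
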