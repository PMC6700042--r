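# Shared fixtures: everything is generated in code at test time.

# hand-built registry with known follow-up structure
toy_records <- function() {
  r <- data.frame(
    patient_id = sprintf("t%02d", 1:8),
    hospital_id = rep(c("h1", "h2"), each = 4),
    age = c(60, 70, 55, 80, 65, 50, 72, 61),
    kps = c(90, 70, 80, 60, 100, 90, 50, 80),
    year = c(2011, 2012, 2013, 2014, 2011, 2012, 2013, 2014),
    gender = c("male", "female", "male", "male", "female", "male", "female", "male"),
    surgery_type = c("resection", "biopsy", "resection", "resection",
                     "biopsy", "resection", "biopsy", "resection"),
    time_days = c(10L, 45L, 730L, 30L, 400L, 900L, 20L, 5L),
    status = c("dead", "dead", "censored", "dead", "dead", "censored",
               "censored", "dead"),
    potential_followup_days = c(800L, 900L, 730L, 1000L, 820L, 900L, 750L, 600L),
    stringsAsFactors = FALSE
  )
  class(r) <- c("registry", "data.frame")
  r
}

# small fast generator config (6 hospitals, ~240 patients)
small_config <- function(...) {
  args <- modifyList(
    list(hospitals = letters[1:6],
         volumes = rep(40L, 6),
         biopsy_fraction = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7),
         p_missing_age = 0, p_missing_kps = 0),
    list(...)
  )
  do.call(generator_config, args)
}

# scale the 14 default hospital volumes to a target cohort size
scaled_volumes <- function(n_target) {
  v <- generator_config()$volumes
  round(v * n_target / sum(v))
}

# independent oracle for exact Poisson funnel limits: brute-force pmf
# enumeration, no CDF/quantile shortcuts
enumerate_limits <- function(E, level) {
  a2 <- (1 - level / 100) / 2
  pmf <- dpois(0:ceiling(E + 12 * sqrt(E) + 20), E)
  cum <- cumsum(pmf)
  lower <- max(which(c(0, cum) <= a2)) - 1   # largest c with P(X < c) <= a2
  upper <- min(which(1 - cum <= a2)) - 1     # smallest c with P(X > c) <= a2
  c(lower, upper) / E
}

# build a pe_fit by hand with known parameter draws (for closed-form checks)
manual_fit <- function(breaks, loglam_draws, beta_draws, covariates,
                       hospitals = c("h1", "h2")) {
  K <- length(breaks) - 1
  n <- nrow(loglam_draws)
  par_names <- c(paste0("beta_", covariates), paste0("loglam", seq_len(K)),
                 paste0("u_", hospitals), "sigma_u")
  draws <- array(0, c(n, 1, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  draws[, 1, seq_along(covariates)] <- beta_draws
  draws[, 1, length(covariates) + seq_len(K)] <- loglam_draws
  structure(list(draws = draws, par_names = par_names,
                 covariates = covariates, breaks = breaks,
                 scaling = list(age_center = 61.4, kps_center = 80,
                                age_scale = 10, kps_scale = 10, ref_year = 2011),
                 hospitals = hospitals, method = "manual", seed = 0,
                 chains = 1, warmup = 0, iter = n),
            class = "pe_fit")
}
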