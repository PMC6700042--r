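# constant-covariate registry: single hospital pair, one-interval baseline
flat_registry <- function(n, lambda, seed) {
  set.seed(seed)
  t <- sample_piecewise_exponential(n, c(0, Inf), lambda)
  r <- data.frame(
    patient_id = sprintf("f%04d", 1:n),
    hospital_id = rep(c("h1", "h2"), length.out = n),
    age = 61.4, kps = 80L, year = 2011L,
    gender = "male", surgery_type = "resection",
    time_days = pmin(as.integer(floor(t)), 2000L),
    status = ifelse(t <= 2000, "dead", "censored"),
    potential_followup_days = 2000L,
    stringsAsFactors = FALSE
  )
  class(r) <- c("registry", "data.frame")
  r
}

test_that("posterior interval hazard matches the Poisson MLE in the flat case", {
  r <- flat_registry(400, 0.002, seed = 21)
  cp <- build_counting_process(r, breaks = c(0, 30, 730, Inf))
  fit <- suppressWarnings(
    fit_hierarchical(cp, chains = 2, warmup = 300, iter = 300, seed = 5)
  )
  s <- fit$summaries
  for (k in 1:3) {
    rows <- cp$interval == k
    mle <- log(sum(cp$event[rows]) / sum(cp$exposure[rows]))
    post <- s[s$parameter == paste0("loglam", k), ]
    psd <- (post$upper95 - post$lower95) / (2 * 1.96)
    expect_lt(abs(post$median - mle), 2 * psd)
  }
})

test_that("single-hospital input is rejected", {
  r <- flat_registry(50, 0.002, seed = 3)
  r$hospital_id <- "h1"
  expect_error(fit_hierarchical(r, breaks = c(0, 30, 730, Inf)),
               "2 hospitals")
})

test_that("rhat separates identical from divergent chains", {
  set.seed(7)
  x <- rnorm(500)
  expect_identical(rhat(cbind(x, x), split = FALSE), 1)
  expect_gt(rhat(cbind(x, x + 5)), 1.1)
})

test_that("laplace approximation agrees with MCMC on the regression block", {
  sim <- generate_registry(small_config(volumes = rep(150L, 6)), seed = 31)
  cc <- complete_case_filter(sim$records)$records
  cp <- build_counting_process(cc)
  fm <- suppressWarnings(
    fit_hierarchical(cp, chains = 2, warmup = 400, iter = 400, seed = 9)
  )
  fl <- fit_hierarchical(cp, method = "laplace", chains = 2, iter = 400, seed = 9)
  bm <- fm$summaries[grep("^beta", fm$summaries$parameter), "median"]
  bl <- fl$summaries[grep("^beta", fl$summaries$parameter), "median"]
  expect_equal(bm, bl, tolerance = 0.08, ignore_attr = TRUE)
})

test_that("fixed-effects log-Poisson fit agrees with Cox partial likelihood", {
  sim <- generate_registry(small_config(volumes = rep(300L, 6)), seed = 17)
  cc <- complete_case_filter(sim$records)$records
  # fine breaks make the piecewise baseline flexible enough to match Cox
  breaks <- c(seq(0, 720, by = 30), 730, 900, 1100, 1300, 1600, Inf)
  hrt <- fit_fixed(cc, breaks = breaks)
  X <- model_covariates(cc)
  cox <- survival::coxph(survival::Surv(cc$time_days + 0.5,
                                        cc$status == "dead") ~ X)
  expect_equal(hrt$estimate, unname(coef(cox)), tolerance = 0.03,
               ignore_attr = TRUE)
})

test_that("degenerate covariates are reported by name", {
  r <- flat_registry(100, 0.003, seed = 5)
  expect_error(fit_fixed(r, breaks = c(0, 30, 730, Inf)), "constant")

  sim <- generate_registry(small_config(), seed = 19)
  cc <- complete_case_filter(sim$records)$records
  hd <- data.frame(hospital_id = letters[1:6], volume = rep(40, 6),
                   academic = c(1, 1, 1, 0, 0, 0))
  # volume constant across hospitals -> zero variance after the join
  expect_error(fit_fixed(cc, hd, hospital_covariates = "log_volume"),
               "constant")
  # two copies of the same hospital covariate -> collinear
  hd2 <- data.frame(hospital_id = letters[1:6],
                    academic = c(1, 1, 1, 0, 0, 0),
                    biopsy_fraction = c(1, 1, 1, 0, 0, 0))
  expect_error(fit_fixed(cc, hd2,
                         hospital_covariates = c("academic", "biopsy_fraction")),
               "collinear")
})

test_that("fit_fixed recovers a true biopsy-fraction effect", {
  # hospitals differ only in biopsy fraction; true log-HR = log(2.09) per
  # +100 percentage points of biopsy share
  set.seed(23)
  H <- 10
  frac <- seq(0.16, 0.73, length.out = H)
  n_h <- 500
  hosp <- rep(letters[1:H], each = n_h)
  lp <- log(2.09) * (rep(frac, each = n_h) - mean(frac))
  t <- sample_piecewise_exponential(H * n_h, c(0, Inf), 0.0022, lp)
  r <- data.frame(
    patient_id = sprintf("b%05d", seq_len(H * n_h)),
    hospital_id = hosp,
    # patient covariates vary but carry no true effect
    age = round(rnorm(H * n_h, 61.4, 12), 1),
    kps = sample(seq(50, 100, 10), H * n_h, replace = TRUE),
    year = rep(c(2011L, 2012L), length.out = H * n_h),
    gender = "male", surgery_type = "resection",
    time_days = pmin(as.integer(floor(t)), 1500L),
    status = ifelse(t <= 1500, "dead", "censored"),
    potential_followup_days = 1500L, stringsAsFactors = FALSE
  )
  class(r) <- c("registry", "data.frame")
  hd <- data.frame(hospital_id = letters[1:H], biopsy_fraction = frac)
  hrt <- fit_fixed(r, hd, hospital_covariates = "biopsy_fraction")
  hr <- hrt$hr[hrt$covariate == "biopsy_fraction"]
  expect_gt(hr, 1.7)
  expect_lt(hr, 2.6)
})

test_that("diagnostics report R-hat per parameter with a pass verdict", {
  r <- flat_registry(200, 0.002, seed = 29)
  fit <- suppressWarnings(
    fit_hierarchical(r, breaks = c(0, 30, 730, Inf),
                     chains = 2, warmup = 200, iter = 200, seed = 2)
  )
  d <- diagnostics(fit)
  expect_true(all(c("parameter", "rhat", "ess") %in% names(d)))
  expect_equal(nrow(d), length(fit$par_names))
  expect_type(attr(d, "pass"), "logical")
})
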