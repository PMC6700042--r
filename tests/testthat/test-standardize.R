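test_that("expected survival reduces to closed forms", {
  # single interval, known lambda draws, null covariates
  lam <- c(0.001, 0.002, 0.005)
  fit <- manual_fit(c(0, Inf), loglam_draws = matrix(log(lam)),
                    beta_draws = matrix(0, 3, 1), covariates = "age")
  X <- matrix(0, 2, 1, dimnames = list(NULL, "age"))
  expect_equal(unname(expected_survival_function(fit, X, 0)),
               matrix(1, 2, 3))
  S30 <- expected_survival_function(fit, X, 30)
  expect_equal(unname(S30), matrix(rep(exp(-30 * lam), each = 2), 2, 3),
               tolerance = 1e-15)
})

test_that("cumulative hazard equals the brute-force overlap sum", {
  set.seed(41)
  for (rep in 1:10) {
    nb <- sample(2:6, 1)
    breaks <- c(0, sort(runif(nb, 10, 900)), Inf)
    haz <- runif(nb + 1, 1e-4, 0.01)
    t <- runif(1, 0, 1200)
    # brute force: integrate the step hazard on a fine grid (Riemann sum)
    grid <- seq(0, t, length.out = 200001)
    k <- findInterval(grid[-1], breaks, left.open = TRUE)
    brute <- sum(haz[k] * diff(grid))
    # Riemann error: at most one grid cell straddles each break
    expect_lt(abs(piecewise_cumhaz(t, breaks, haz) - brute),
              (nb + 2) * max(haz) * t / 200000)
  }
})

test_that("survival is monotone in t for every draw", {
  set.seed(43)
  lam <- matrix(log(runif(40, 1e-4, 0.01)), 10, 4)
  fit <- manual_fit(c(0, 30, 365, 730, Inf), loglam_draws = lam,
                    beta_draws = matrix(rnorm(10, 0, 0.3)), covariates = "age")
  X <- matrix(rnorm(5), 5, 1, dimnames = list(NULL, "age"))
  ts <- c(0, 15, 30, 100, 400, 730, 1500)
  S <- sapply(ts, function(t) expected_survival_function(fit, X, t))
  expect_true(all(diff(t(matrix(S, 50, length(ts)))) <= 1e-14))
})

test_that("expected events are linear and additive over hospitals", {
  fit <- manual_fit(c(0, 30, 730, Inf),
                    loglam_draws = matrix(log(0.002), 2, 3),
                    beta_draws = matrix(0, 2, 2), covariates = c("age", "kps"),
                    hospitals = c("h1", "h2"))
  r <- toy_records()
  r$age <- 61.4; r$kps <- 80L; r$year <- 2011L
  r$status <- "dead"; r$time_days <- 40L
  class(r) <- c("registry", "data.frame")
  ee <- expected_events(fit, r, "early_death")
  # identical patients: expected = m * common probability
  p <- 1 - exp(-30 * 0.002)
  expect_equal(ee$expected, c(4 * p, 4 * p), tolerance = 1e-12)
  # additivity: pooled expected equals the sum over hospitals
  r2 <- r; r2$hospital_id <- "pooled"
  class(r2) <- c("registry", "data.frame")
  ee2 <- expected_events(fit, r2, "early_death")
  expect_equal(sum(ee$expected), ee2$expected, tolerance = 1e-12)
})

test_that("late-survival probability respects S(730) <= S(30) per draw", {
  set.seed(47)
  lam <- matrix(log(runif(24, 1e-4, 0.01)), 8, 3)
  fit <- manual_fit(c(0, 30, 730, Inf), loglam_draws = lam,
                    beta_draws = matrix(rnorm(8, 0, 0.2)), covariates = "age")
  X <- matrix(rnorm(4), 4, 1, dimnames = list(NULL, "age"))
  expect_true(all(expected_survival_function(fit, X, 730) <=
                    expected_survival_function(fit, X, 30) + 1e-14))
})

test_that("O/E ratios are exact algebra with guarded degenerate input", {
  expect_equal(oe_ratios(c(a = 6), observed = 6)$ratio, 1)
  expect_equal(oe_ratios(c(i = 0.89), observed = 0)$ratio, 0)
  expect_error(oe_ratios(c(x = 0), observed = 2), "positive")
  set.seed(49)
  expc <- runif(20, 0.5, 30)
  obsv <- rpois(20, expc)
  tab <- oe_ratios(setNames(expc, paste0("h", 1:20)), observed = obsv)
  expect_equal(tab$ratio * tab$expected, as.numeric(obsv), tolerance = 1e-14)
})

test_that("median-of-sums and plugin summaries agree in the symmetric case", {
  lam <- matrix(log(0.002) + c(-0.2, 0, 0.2), 3, 1)
  fit <- manual_fit(c(0, 30, 730, Inf),
                    loglam_draws = cbind(lam[, 1], lam[, 1], lam[, 1]),
                    beta_draws = matrix(0, 3, 2), covariates = c("age", "kps"))
  r <- toy_records()
  r$age <- 61.4; r$kps <- 80L; r$year <- 2011L
  r$status <- "dead"; r$time_days <- 40L
  class(r) <- c("registry", "data.frame")
  a <- expected_events(fit, r, "early_death", summary = "median_of_sums")
  b <- expected_events(fit, r, "early_death", summary = "plugin")
  expect_equal(a$expected, b$expected, tolerance = 1e-12)
})
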