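test_that("aggregated and patient-expanded logistic fits coincide exactly", {
  set.seed(61)
  agg <- data.frame(
    hospital_id = letters[1:8],
    n = c(80, 220, 290, 100, 160, 270, 200, 350),
    volume = c(80, 220, 290, 100, 160, 270, 200, 350)
  )
  agg$events <- rbinom(8, agg$n, plogis(-2.9 - 0.3 * (log(agg$volume) - 5)))
  fa <- patient_level_logistic(agg, "early_death", "log_volume")
  # expand to one Bernoulli row per patient and refit through glm directly
  y <- unlist(mapply(function(e, n) c(rep(1, e), rep(0, n - e)),
                     agg$events, agg$n))
  x <- rep(log(agg$volume), agg$n)
  fp <- glm(y ~ x, family = binomial(), control = list(epsilon = 1e-12))
  expect_equal(fa$slope, unname(coef(fp)[2]), tolerance = 1e-8)
  expect_equal(fa$intercept, unname(coef(fp)[1]), tolerance = 1e-8)
  expect_equal(logLik(glm(cbind(events, n - events) ~ log(volume),
                          family = binomial(), data = agg))[1] -
                 sum(lchoose(agg$n, agg$events)),
               logLik(fp)[1], tolerance = 1e-6)
})

test_that("equal rates give a zero slope and boundary algebra holds", {
  agg <- data.frame(hospital_id = letters[1:5], n = rep(200, 5),
                    events = rep(10, 5), volume = c(80, 120, 180, 250, 350))
  f <- patient_level_logistic(agg, "early_death", "log_volume")
  expect_lt(abs(f$slope), 1e-6)
  expect_error(boundary_volume(list(slope = 0, transform = "log",
                                    intercept = 0, pooled_rate = 0.05)),
               "logistic_fit")

  # intercept = logit(rate) forces the boundary to v = 1
  f2 <- f
  f2$slope <- -0.5
  f2$intercept <- qlogis(0.05)
  expect_equal(boundary_volume(f2, reference_rate = 0.05), 1)

  # re-fitting the intercept through a fixed crossing point leaves v unchanged
  v0 <- 180
  for (b in c(-0.39, -0.195)) {
    a <- qlogis(0.052) - b * log(v0)
    f3 <- f
    f3$slope <- b
    f3$intercept <- a
    expect_equal(boundary_volume(f3, reference_rate = 0.052), v0,
                 tolerance = 1e-9)
  }
})

test_that("relative_effect reports both conventions", {
  re <- relative_effect(-0.39, 0.10)
  expect_equal(re$exact, exp(-0.39 * log(1.1)) - 1)
  expect_equal(re$approx, -0.039)
  expect_equal(relative_effect(0, 0.10)$exact, 0)
  expect_equal(relative_effect(-0.39, 0)$approx, 0)
})

test_that("degenerate covariates and separation are handled", {
  agg <- data.frame(hospital_id = letters[1:4], n = rep(100, 4),
                    events = c(5, 8, 3, 9), volume = rep(100, 4))
  expect_error(patient_level_logistic(agg, "early_death", "log_volume"),
               "zero-variance")
  sep <- data.frame(hospital_id = letters[1:4], n = rep(50, 4),
                    events = c(0, 0, 50, 50), academic = c(0, 0, 1, 1))
  f <- patient_level_logistic(sep, "early_death", "academic")
  expect_true(f$separation)
})

test_that("record-level input matches the aggregate path", {
  sim <- generate_registry(small_config(), seed = 67)
  r <- sim$records
  hd <- data.frame(hospital_id = letters[1:6],
                   volume = as.numeric(table(r$hospital_id)[letters[1:6]]) +
                     c(10, -5, 0, 3, -2, 8))
  f1 <- patient_level_logistic(r, "early_death", "log_volume",
                               hospital_data = hd)
  obs <- observable_at(r, 30)
  agg <- data.frame(
    hospital_id = letters[1:6],
    events = as.integer(rowsum(as.integer(obs$dead_by_horizon), obs$hospital_id)),
    n = as.integer(table(obs$hospital_id)[letters[1:6]])
  )
  agg <- merge(agg, hd, by = "hospital_id")
  f2 <- patient_level_logistic(agg, "early_death", "log_volume")
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)
  expect_equal(f1$n, f2$n)
})

test_that("coverage of the null volume effect is near nominal", {
  # no volume effect in truth: the Wald interval should cover 0 most times
  hits <- 0
  reps <- 12
  for (s in seq_len(reps)) {
    sim <- generate_registry(small_config(volumes = c(40L, 80L, 120L, 160L,
                                                      240L, 320L)), seed = 100 + s)
    smry <- summarize_hospitals(complete_case_filter(sim$records)$records,
                                all_records = sim$records)
    smry$academic <- FALSE
    f <- explore_hospital_factors(smry, "early_death", "log_volume")
    ci <- f$slope + c(-1.96, 1.96) * f$se_slope
    hits <- hits + (ci[1] <= 0 && 0 <= ci[2])
  }
  expect_gte(hits / reps, 0.75)
})
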