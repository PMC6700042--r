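test_that("read_registry parses dates and computes follow-up times", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,hospital_id,age,kps,year,gender,surgery_type,surgery_date,death_date,last_contact_date",
    "p1,h1,60,90,2012,male,resection,2012-05-01,2012-05-31,",
    "p2,h1,70,80,2013,female,biopsy,2013-02-01,,2015-06-01",
    "p3,h2,55,70,2014,male,resection,2014-03-01,,"
  ), f)
  r <- read_registry(f, lookup_date = "2016-03-01")
  expect_s3_class(r, "registry")
  # death 30 days after surgery
  expect_equal(r$time_days[1], 30L)
  expect_equal(r$status[1], "dead")
  # censored at last contact, before lookup
  expect_equal(r$status[2], "censored")
  expect_equal(r$time_days[2], as.integer(as.Date("2015-06-01") - as.Date("2013-02-01")))
  # censored administratively at lookup
  expect_equal(r$time_days[3], as.integer(as.Date("2016-03-01") - as.Date("2014-03-01")))
  expect_equal(r$potential_followup_days[3], r$time_days[3])
})

test_that("read_registry handles the empty and malformed cases", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,hospital_id,age,kps,year,gender,surgery_type,time_days,status,potential_followup_days", f)
  expect_equal(nrow(read_registry(f)), 0)

  writeLines(c(
    "patient_id,hospital_id,age,kps,year,gender,surgery_type,time_days,status,potential_followup_days",
    "p1,h1,60,90,2012,male,resection,ten,dead,100"
  ), f)
  expect_error(read_registry(f), "row 1.*time_days")

  writeLines(c(
    "patient_id,hospital_id,age,kps,year,gender,surgery_type,time_days,status,potential_followup_days",
    "p1,h1,60,90,2012,male,resection,-5,dead,100"
  ), f)
  expect_error(read_registry(f), "negative")
})

test_that("registry round-trips through write/read unchanged", {
  sim <- generate_registry(generator_config(), seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_registry(sim$records, f)
  back <- read_registry(f)
  for (cn in c("patient_id", "hospital_id", "kps", "year", "gender",
               "surgery_type", "time_days", "status", "potential_followup_days")) {
    expect_equal(back[[cn]], sim$records[[cn]], info = cn)
  }
  expect_equal(back$age, sim$records$age, tolerance = 1e-8)
  expect_equal(nrow(back), sum(generator_config()$volumes))
})

test_that("complete_case_filter drops only missing model covariates", {
  r <- toy_records()
  r$gender[1] <- NA      # not a covariate: kept
  r$kps[2] <- NA         # covariate: dropped
  r$age[5] <- NA         # covariate: dropped
  out <- complete_case_filter(r)
  expect_equal(nrow(out$records), 6)
  expect_false(any(out$records$patient_id %in% c("t02", "t05")))
  expect_true("t01" %in% out$records$patient_id)
  ex <- out$exclusions
  expect_equal(sum(ex$n_excluded), 2)
  expect_equal(ex$missing_kps[ex$hospital_id == "h1"], 1L)
  expect_equal(ex$missing_age[ex$hospital_id == "h2"], 1L)
})

test_that("observable_at applies the closed-boundary outcome definitions", {
  r <- toy_records()
  # censored at day 20 with potential 750: lost to follow-up before 30 days
  obs30 <- observable_at(r, 30)
  expect_false("t07" %in% obs30$patient_id)
  # dead at day 10: observable at any horizon, not alive at 2 years
  obs730 <- observable_at(r, 730)
  expect_true("t01" %in% obs730$patient_id)
  expect_true(obs730$dead_by_horizon[obs730$patient_id == "t01"])
  # dead exactly at the horizon counts as dead by the horizon
  expect_true(obs30$dead_by_horizon[obs30$patient_id == "t04"])
  # censored exactly at 730 with potential 730: survivor
  expect_false(obs730$dead_by_horizon[obs730$patient_id == "t03"])
  # censored at 900 with potential >= 730: alive at 2 years
  expect_false(obs730$dead_by_horizon[obs730$patient_id == "t06"])
})

test_that("observability is monotone under administrative censoring", {
  sim <- generate_registry(small_config(), seed = 5)
  r <- sim$records
  ids730 <- observable_at(r, 730)$patient_id
  ids30 <- observable_at(r, 30)$patient_id
  expect_true(all(ids730 %in% ids30))
})

test_that("summarize_hospitals satisfies its invariants", {
  sim <- generate_registry(small_config(), seed = 9)
  cc <- complete_case_filter(sim$records)$records
  academic <- setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), letters[1:6])
  s <- summarize_hospitals(cc, academic = academic, all_records = sim$records)
  per <- s[s$hospital_id != "overall", ]
  ov <- s[s$hospital_id == "overall", ]
  expect_true(all(per$deaths_30d <= per$observable_30d))
  expect_true(all(per$observable_30d <= per$n_complete))
  expect_true(all(per$survivors_2y <= per$observable_2y))
  for (cn in c("n_total", "n_complete", "n_resection", "n_biopsy",
               "deaths_30d", "observable_30d", "survivors_2y", "observable_2y")) {
    expect_equal(sum(per[[cn]]), ov[[cn]], info = cn)
  }
  expect_equal(per$biopsy_pct,
               100 * per$n_biopsy / (per$n_biopsy + per$n_resection))
  expect_error(summarize_hospitals(cc, academic = academic[-1],
                                   all_records = sim$records),
               "academic map")
})

test_that("a hospital with zero deaths gets 0% mortality", {
  r <- toy_records()
  r$status <- "censored"
  r$time_days <- r$potential_followup_days
  s <- summarize_hospitals(r)
  expect_equal(s$mortality_30d_pct, rep(0, nrow(s)))
})
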