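#' Default registry column schema
#'
#' Maps the canonical patient-record fields onto the column names expected in
#' a registry CSV. Override entries to read files with different headers.
#' Either precomputed follow-up columns (`time_days`, `status`,
#' `potential_followup_days`) or raw date columns (`surgery_date`,
#' `death_date`, `last_contact_date`, together with a lookup date) must be
#' present.
#'
#' @param ... name = "column" overrides.
#' @return Named list of column names.
#' @export
registry_schema <- function(...) {
  schema <- list(
    patient_id = "patient_id", hospital_id = "hospital_id",
    age = "age", kps = "kps", year = "year", gender = "gender",
    surgery_type = "surgery_type",
    time_days = "time_days", status = "status",
    potential_followup_days = "potential_followup_days",
    surgery_date = "surgery_date", death_date = "death_date",
    last_contact_date = "last_contact_date"
  )
  modifyList(schema, list(...))
}

.canonical_cols <- c("patient_id", "hospital_id", "age", "kps", "year",
                     "gender", "surgery_type", "time_days", "status",
                     "potential_followup_days")

#' Read a patient-level registry from CSV
#'
#' One row per surgical case. Dates are ISO-8601; day 0 is the day of surgery.
#' When `time_days`/`status` are not pre-computed they are derived from the
#' date columns: a patient is `dead` if a death date at or before the lookup
#' date exists, follow-up ends at the earliest of death, last contact and the
#' lookup date, and potential follow-up runs from surgery to the lookup date.
#'
#' @param path CSV file with a header.
#' @param schema Column mapping from [registry_schema()].
#' @param lookup_date ISO date string; the administrative date at which vital
#'   status was established. Required when deriving times from dates.
#' @return A `registry` data frame of patient records.
#' @export
read_registry <- function(path, schema = registry_schema(), lookup_date = NULL) {
  stopifnot(file.exists(path))
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- function(field) {
    col <- schema[[field]]
    if (!col %in% names(raw)) {
      stop(sprintf("registry file lacks column '%s' (field '%s')", col, field))
    }
    raw[[col]]
  }
  have <- function(field) schema[[field]] %in% names(raw)

  n <- nrow(raw)
  rec <- data.frame(
    patient_id = as.character(need("patient_id")),
    hospital_id = as.character(need("hospital_id")),
    stringsAsFactors = FALSE
  )
  num_field <- function(field, integer = FALSE) {
    x <- need(field)
    bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
    if (any(bad)) {
      stop(sprintf("malformed row %d: field '%s' value '%s' is not numeric",
                   which(bad)[1], field, x[which(bad)[1]]))
    }
    out <- suppressWarnings(as.numeric(x))
    if (integer) out <- as.integer(round(out))
    out
  }
  rec$age <- num_field("age")
  rec$kps <- if (have("kps")) num_field("kps", integer = TRUE) else NA_integer_
  rec$year <- if (have("year")) num_field("year", integer = TRUE) else NA_integer_
  rec$gender <- if (have("gender")) as.character(need("gender")) else NA_character_
  rec$surgery_type <- if (have("surgery_type")) as.character(need("surgery_type")) else NA_character_

  if (have("time_days") && have("status")) {
    rec$time_days <- num_field("time_days", integer = TRUE)
    rec$status <- as.character(need("status"))
    rec$potential_followup_days <- if (have("potential_followup_days")) {
      num_field("potential_followup_days", integer = TRUE)
    } else {
      NA_integer_
    }
  } else {
    if (is.null(lookup_date)) {
      stop("lookup_date is required when time_days/status are not pre-computed")
    }
    lookup <- as.Date(lookup_date)
    parse_date <- function(field) {
      x <- need(field)
      x[x %in% c("", "NA")] <- NA
      d <- as.Date(x, format = "%Y-%m-%d")
      bad <- !is.na(x) & is.na(d)
      if (any(bad)) {
        stop(sprintf("malformed row %d: field '%s' value '%s' is not an ISO date",
                     which(bad)[1], field, x[which(bad)[1]]))
      }
      d
    }
    surg <- parse_date("surgery_date")
    death <- if (have("death_date")) parse_date("death_date") else as.Date(rep(NA, n))
    last <- if (have("last_contact_date")) parse_date("last_contact_date") else as.Date(rep(NA, n))
    if (anyNA(surg)) {
      stop(sprintf("malformed row %d: missing surgery_date", which(is.na(surg))[1]))
    }
    dead <- !is.na(death) & death <= lookup
    end <- pmin(ifelse(dead, death, Inf), ifelse(is.na(last), Inf, last),
                as.numeric(lookup))
    rec$time_days <- as.integer(end - as.numeric(surg))
    rec$status <- ifelse(dead, "dead", "censored")
    rec$potential_followup_days <- as.integer(lookup - surg)
    rec$surgery_date <- as.character(surg)
  }

  bad_t <- which(!is.na(rec$time_days) & rec$time_days < 0)
  if (length(bad_t)) {
    stop(sprintf("malformed row %d: field 'time_days' is negative (%d)",
                 bad_t[1], rec$time_days[bad_t[1]]))
  }
  bad_s <- which(!rec$status %in% c("dead", "censored"))
  if (length(bad_s)) {
    stop(sprintf("malformed row %d: field 'status' must be dead/censored, got '%s'",
                 bad_s[1], rec$status[bad_s[1]]))
  }
  class(rec) <- c("registry", "data.frame")
  rec
}

#' Write a registry to CSV
#'
#' Writes the canonical columns so that `read_registry(write_registry(x))`
#' round-trips field-for-field.
#'
#' @param records A `registry` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(records, path) {
  cols <- intersect(c(.canonical_cols, "surgery_date"), names(records))
  write.csv(records[, cols, drop = FALSE], path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Restrict to complete cases for the risk model
#'
#' Keeps records with nonmissing age, Karnofsky performance status and
#' treatment year (the model covariates; gender and surgery type are not
#' covariates and missingness there does not exclude). Returns the kept
#' records together with an exclusion log counting missing fields per
#' hospital.
#'
#' @param records A `registry` data frame.
#' @return List with `records` (kept rows) and `exclusions` (data frame:
#'   hospital_id, missing_age, missing_kps, missing_year, n_excluded).
#' @export
complete_case_filter <- function(records) {
  miss_age <- is.na(records$age)
  miss_kps <- is.na(records$kps)
  miss_year <- is.na(records$year)
  drop <- miss_age | miss_kps | miss_year
  hosp <- sort(unique(records$hospital_id))
  excl <- data.frame(
    hospital_id = hosp,
    missing_age = as.integer(rowsum(as.integer(miss_age), records$hospital_id)[hosp, 1]),
    missing_kps = as.integer(rowsum(as.integer(miss_kps), records$hospital_id)[hosp, 1]),
    missing_year = as.integer(rowsum(as.integer(miss_year), records$hospital_id)[hosp, 1]),
    n_excluded = as.integer(rowsum(as.integer(drop), records$hospital_id)[hosp, 1]),
    stringsAsFactors = FALSE
  )
  kept <- records[!drop, , drop = FALSE]
  class(kept) <- class(records)
  list(records = kept, exclusions = excl)
}

#' Patients whose outcome at a horizon is determined
#'
#' A patient is observable at horizon h when either death occurred by h
#' (time_days <= h, closed boundary) or potential follow-up reaches h
#' (potential_followup_days >= h). The returned subset carries an `outcome`
#' column: `dead_by_horizon` is TRUE when the patient died within h days.
#'
#' @param records A `registry` data frame.
#' @param horizon_days Positive integer horizon (30 for early mortality,
#'   730 for late survival).
#' @return Subset of `records` with a logical `dead_by_horizon` column.
#' @export
observable_at <- function(records, horizon_days) {
  stopifnot(horizon_days > 0)
  dead_by <- records$status == "dead" & records$time_days <= horizon_days
  pf <- records$potential_followup_days
  pf[is.na(pf)] <- records$time_days[is.na(pf)]  # fall back: observed follow-up
  keep <- dead_by | pf >= horizon_days
  # a patient censored before the horizon with enough potential follow-up is
  # lost to follow-up: outcome genuinely unknown, exclude as well
  lost <- records$status == "censored" & records$time_days < horizon_days
  keep <- keep & !lost
  out <- records[keep, , drop = FALSE]
  out$dead_by_horizon <- dead_by[keep]
  class(out) <- class(records)
  out
}

#' Per-hospital summary table
#'
#' Aggregates a complete-case registry into one row per hospital plus an
#' `overall` pseudo-row: volumes, surgery mix, 30-day mortality and 2-year
#' survival with their observable denominators, age moments and KPS/year
#' distributions. Percentages are kept as raw ratios; display rounding is the
#' caller's business.
#'
#' @param records Complete-case `registry` data frame.
#' @param academic Named logical vector (hospital_id -> academic setting), or
#'   NULL to omit the flag.
#' @param all_records Optional unfiltered registry used for total volumes;
#'   defaults to `records`.
#' @return A `hospital_summary` data frame.
#' @export
summarize_hospitals <- function(records, academic = NULL, all_records = NULL) {
  if (is.null(all_records)) all_records <- records
  hosp <- sort(unique(all_records$hospital_id))
  if (!is.null(academic)) {
    unknown <- setdiff(hosp, names(academic))
    if (length(unknown)) {
      stop("hospitals missing from academic map: ", paste(unknown, collapse = ", "))
    }
  }
  obs30 <- observable_at(records, 30L)
  obs730 <- observable_at(records, 730L)
  cnt <- function(ids, subset = rep(TRUE, length(ids))) {
    tab <- table(factor(ids[subset], levels = hosp))
    as.integer(tab)
  }
  one <- function(ids, values, fun) {
    sapply(hosp, function(h) {
      v <- values[ids == h]
      if (!length(v)) NA_real_ else fun(v)
    })
  }
  st <- records$surgery_type
  smry <- data.frame(
    hospital_id = hosp,
    n_total = cnt(all_records$hospital_id),
    n_complete = cnt(records$hospital_id),
    n_resection = cnt(records$hospital_id, !is.na(st) & st == "resection"),
    n_biopsy = cnt(records$hospital_id, !is.na(st) & st == "biopsy"),
    deaths_30d = cnt(obs30$hospital_id, obs30$dead_by_horizon),
    observable_30d = cnt(obs30$hospital_id),
    survivors_2y = cnt(obs730$hospital_id, !obs730$dead_by_horizon),
    observable_2y = cnt(obs730$hospital_id),
    age_mean = one(records$hospital_id, records$age, mean),
    age_sd = one(records$hospital_id, records$age, sd),
    stringsAsFactors = FALSE
  )
  overall <- data.frame(
    hospital_id = "overall",
    n_total = nrow(all_records), n_complete = nrow(records),
    n_resection = sum(smry$n_resection), n_biopsy = sum(smry$n_biopsy),
    deaths_30d = sum(smry$deaths_30d), observable_30d = sum(smry$observable_30d),
    survivors_2y = sum(smry$survivors_2y), observable_2y = sum(smry$observable_2y),
    age_mean = mean(records$age), age_sd = sd(records$age),
    stringsAsFactors = FALSE
  )
  out <- rbind(smry, overall)
  if (!is.null(academic)) {
    out$academic <- c(unname(academic[hosp]), NA)
  }
  out <- add_summary_rates(out)
  attr(out, "kps_counts") <- table(factor(records$kps, levels = seq(10, 100, 10)))
  attr(out, "year_counts") <- table(records$year)
  class(out) <- c("hospital_summary", "data.frame")
  out
}

#' Add outcome-rate columns to an aggregate hospital table
#'
#' Computes biopsy percentage (denominator: biopsy + resection), 30-day
#' mortality and 2-year survival as raw percentages from the count columns.
#' Works both on tables built by [summarize_hospitals()] and on externally
#' supplied aggregate tables such as [hospital_aggregates()].
#'
#' @param tab Data frame with count columns `n_biopsy`, `n_resection`,
#'   `deaths_30d`, `observable_30d`, `survivors_2y`, `observable_2y`.
#' @return `tab` with `biopsy_pct`, `mortality_30d_pct`, `survival_2y_pct`.
#' @export
add_summary_rates <- function(tab) {
  den <- tab$n_biopsy + tab$n_resection
  tab$biopsy_pct <- ifelse(den > 0, 100 * tab$n_biopsy / den, NA_real_)
  tab$mortality_30d_pct <- ifelse(tab$observable_30d > 0,
                                  100 * tab$deaths_30d / tab$observable_30d, NA_real_)
  tab$survival_2y_pct <- ifelse(tab$observable_2y > 0,
                                100 * tab$survivors_2y / tab$observable_2y, NA_real_)
  tab
}

#' Aggregate counts of the 14-hospital glioblastoma registry
#'
#' Published per-hospital aggregates of a national four-year (2011-2014)
#' glioblastoma-surgery quality registry: volumes, complete-case counts,
#' surgery mix, 30-day deaths and 2-year survivors with their observable
#' denominators, age moments and academic setting. These printed counts are
#' the deterministic test bed for the Table-1-style arithmetic and the
#' hospital-factor regressions.
#'
#' @param overall Append a pooled `overall` row (default TRUE).
#' @return Data frame with one row per hospital (a..n), rate columns added.
#' @export
hospital_aggregates <- function(overall = TRUE) {
  path <- system.file("extdata", "hospital_aggregates.csv", package = "oefunnel")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$hospital <- as.character(tab$hospital)
  names(tab)[names(tab) == "hospital"] <- "hospital_id"
  if (overall) {
    num <- vapply(tab, is.numeric, logical(1))
    tot <- tab[1, , drop = FALSE]
    tot$hospital_id <- "overall"
    for (cn in names(tab)[num]) tot[[cn]] <- sum(tab[[cn]])
    # means/SDs do not pool by summation; recompute the pooled age mean,
    # leave the pooled SD unavailable
    tot$age_mean <- sum(tab$age_mean * tab$n_complete) / sum(tab$n_complete)
    tot$age_sd <- NA_real_
    tot$median_os_months <- NA_real_
    tot$academic <- NA
    tab <- rbind(tab, tot)
  }
  add_summary_rates(tab)
}

#' Overall covariate distributions of the registry
#'
#' Cohort-level distributions used as synthetic-generator defaults: KPS
#' ladder counts (including missing), treatment-year counts, age moments and
#' missing-age count, over all 2,409 registered patients.
#'
#' @return List with `kps_counts`, `kps_missing`, `year_counts`, `age_mean`,
#'   `age_sd`, `age_missing`, `n_patients`.
#' @export
registry_margins <- function() {
  list(
    kps_counts = c(`10` = 2, `20` = 22, `30` = 13, `40` = 21, `50` = 127,
                   `60` = 199, `70` = 357, `80` = 581, `90` = 790, `100` = 216),
    kps_missing = 81,
    year_counts = c(`2011` = 523, `2012` = 601, `2013` = 609, `2014` = 676),
    age_mean = 61.4, age_sd = 12.2, age_missing = 10,
    n_patients = 2409
  )
}
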