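DAYS_PER_MONTH <- 30.44

#' Kaplan-Meier curves per hospital
#'
#' Product-limit estimator with right censoring, per hospital and pooled.
#' Medians are read off each curve as the first time with `S(t) <= 0.5`,
#' computed in days and converted to months at 30.44 days/month.
#'
#' @param records A `registry`.
#' @param by Grouping column (default hospital); NULL pools everyone.
#' @return List with `fit` (a `survfit` object) and `medians` (data frame:
#'   group, n, events, median_days, median_months).
#' @export
kaplan_meier <- function(records, by = "hospital_id") {
  dead <- as.integer(records$status == "dead")
  if (is.null(by)) {
    sf <- survival::survfit(survival::Surv(records$time_days, dead) ~ 1)
    groups <- "all"
    strata_id <- rep("all", length(dead))
  } else {
    grp <- records[[by]]
    keep_groups <- names(which(table(grp) > 0))
    sf <- survival::survfit(survival::Surv(records$time_days, dead) ~ grp)
    groups <- sub("^grp=", "", names(sf$strata))
    strata_id <- grp
  }
  med <- summary(sf)$table
  if (is.null(dim(med))) med <- t(as.matrix(med))
  medians <- data.frame(
    group = groups,
    n = as.integer(med[, "records"]),
    events = as.integer(med[, "events"]),
    median_days = as.numeric(med[, "median"]),
    stringsAsFactors = FALSE
  )
  medians$median_months <- medians$median_days / DAYS_PER_MONTH
  list(fit = sf, medians = medians)
}

#' Plot per-hospital Kaplan-Meier curves
#'
#' @param km Result of [kaplan_meier()].
#' @param file Optional PNG path.
#' @param main Title.
#' @return Invisibly NULL.
#' @export
plot_km <- function(km, file = NULL, main = "Overall survival per hospital") {
  if (!is.null(file)) {
    png(file, width = 900, height = 700, res = 110)
    on.exit(dev.off())
  }
  ng <- max(1, length(km$fit$strata))
  cols <- grDevices::hcl.colors(max(ng, 2), "Dark 3")
  plot(km$fit, col = cols[seq_len(ng)], xlab = "Months since surgery",
       ylab = "Survival", xscale = DAYS_PER_MONTH, main = main)
  if (ng > 1) {
    legend("topright", legend = km$medians$group, col = cols[seq_len(ng)],
           lty = 1, cex = 0.7, ncol = 2)
  }
  invisible(NULL)
}

#' Observed versus expected survival per hospital
#'
#' One panel per hospital: the observed Kaplan-Meier curve (with censor
#' marks), the risk-standardized expected curve at random effect 0 (average
#' hospital), and the fitted curve using the hospital's posterior-median
#' frailty; vertical guides at 30 and 730 days. Two closing panels show the
#' deviation between observed and expected deaths per hospital, as an
#' absolute difference and as a ratio.
#'
#' @param fit A `pe_fit`.
#' @param records Complete-case `registry`.
#' @param file Optional PNG path.
#' @return Invisibly, a data frame of per-hospital observed/expected deaths.
#' @export
plot_observed_vs_expected <- function(fit, records, file = NULL) {
  hosp <- fit$hospitals
  if (!is.null(file)) {
    png(file, width = 1400, height = 300 * ceiling((length(hosp) + 2) / 4),
        res = 100)
  }
  op <- par(mfrow = c(ceiling((length(hosp) + 2) / 4), 4),
            mar = c(3.5, 3.5, 2, 0.5), mgp = c(2, 0.7, 0))
  on.exit({
    par(op)
    if (!is.null(file)) dev.off()  # par must be restored before the device closes
  })
  tgrid <- seq(0, 1200, by = 15)
  umed <- fit$summaries$median[match(paste0("u_", hosp), fit$summaries$parameter)]
  dev <- data.frame(hospital_id = hosp, observed = NA_real_, expected = NA_real_)
  for (i in seq_along(hosp)) {
    rec_h <- records[records$hospital_id == hosp[i], , drop = FALSE]
    class(rec_h) <- class(records)
    km <- kaplan_meier(rec_h, by = NULL)
    Sexp <- vapply(tgrid, function(t) {
      mean(apply(expected_survival_function(fit, rec_h, t), 1, median))
    }, numeric(1))
    Sfit <- vapply(tgrid, function(t) {
      mean(apply(expected_survival_function(fit, rec_h, t, u = umed[i]), 1, median))
    }, numeric(1))
    plot(km$fit, conf.int = FALSE, mark.time = TRUE, lwd = 2,
         xlab = "Days", ylab = "Survival", main = paste("Hospital", hosp[i]),
         xlim = c(0, 1200))
    lines(tgrid, Sexp, col = "blue")
    lines(tgrid, Sfit, col = "black", lwd = 0.7)
    abline(v = c(30, 730), lty = 3, col = "grey50")
    p_dead <- 1 - expected_survival_function(fit, rec_h, 730)
    dev$expected[i] <- median(colSums(p_dead))
    dev$observed[i] <- sum(rec_h$status == "dead" & rec_h$time_days <= 730)
  }
  plot(seq_along(hosp), dev$observed - dev$expected, pch = 16,
       xlab = "Hospital", ylab = "Observed - expected deaths", xaxt = "n",
       main = "Deviation (absolute)")
  axis(1, seq_along(hosp), hosp)
  abline(h = 0, lty = 2)
  plot(seq_along(hosp), dev$observed / dev$expected, pch = 16,
       xlab = "Hospital", ylab = "Observed / expected deaths", xaxt = "n",
       main = "Deviation (ratio)")
  axis(1, seq_along(hosp), hosp)
  abline(h = 1, lty = 2)
  invisible(dev)
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON, a YAML subset) with any of: `seed`, `registry`,
#' `out_dir`, `lookup_date`, `funnel_method`, `model` (chains, warmup, iter,
#' method, breaks), `academic` (list hospital: yes/no), `generator`
#' (overrides for [generator_config()]).
#'
#' @param path Config file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full profiling pipeline
#'
#' Simulate (or read) a registry, filter to complete cases, summarize
#' hospitals, fit the hierarchical model, risk-standardize both outcomes,
#' flag funnel outliers, run the hospital-factor regressions, and write the
#' report bundle (summary CSV, fit JSON, ratios/flags CSV, funnel and KM
#' PNGs, log). Numeric outputs are deterministic given the seed.
#'
#' @param config List as from [read_pipeline_config()]; unspecified entries
#'   fall back to defaults.
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config = list()) {
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% "oefunnel_report"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "pipeline.log")
  logline <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), sprintf(...)),
        file = logfile, append = TRUE)
  }
  cat("", file = logfile)
  logline("oefunnel %s | seed %d", as.character(packageVersion("oefunnel")), seed)

  stage <- "simulate/read"
  res <- tryCatch({
    if (!is.null(config$registry)) {
      records <- read_registry(config$registry,
                               lookup_date = config$lookup_date %||% NULL)
      truth <- NULL
    } else {
      gcfg <- do.call(generator_config, config$generator %||% list())
      sim <- generate_registry(gcfg, seed)
      records <- sim$records
      truth <- sim$truth
    }
    logline("stage %s: %d records in", stage, nrow(records))

    stage <- "complete_case_filter"
    cc <- complete_case_filter(records)
    logline("stage %s: %d kept / %d", stage, nrow(cc$records), nrow(records))

    stage <- "summarize_hospitals"
    academic <- if (!is.null(config$academic)) {
      unlist(config$academic)
    } else {
      setNames(seq_along(unique(records$hospital_id)) <= 7,
               sort(unique(records$hospital_id)))
    }
    smry <- summarize_hospitals(cc$records, academic = academic,
                                all_records = records)
    write.csv(smry, file.path(out_dir, "hospital_summary.csv"), row.names = FALSE)

    stage <- "hazard_model"
    mc <- config$model %||% list()
    fit <- fit_hierarchical(cc$records,
                            breaks = mc$breaks %||% default_breaks(),
                            chains = mc$chains %||% 4,
                            warmup = mc$warmup %||% 1000,
                            iter = mc$iter %||% 1000,
                            seed = seed, method = mc$method %||% "mcmc")
    jsonlite::write_json(
      list(summaries = fit$summaries, converged = fit$converged,
           seed = seed, method = fit$method, breaks = fit$breaks),
      file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA, na = "null")
    if (!fit$converged) {
      logline("stage %s: convergence FAILED", stage)
    }

    stage <- "standardization"
    ratios <- standardize(fit, cc$records)
    write.csv(ratios, file.path(out_dir, "ratios.csv"), row.names = FALSE)

    stage <- "funnel_control"
    flagged <- flag_outliers(ratios, method = config$funnel_method %||% "interpolated")
    write.csv(flagged, file.path(out_dir, "flags.csv"), row.names = FALSE)
    plot_funnel(flagged[flagged$kind == "early_death", ],
                file = file.path(out_dir, "funnel_early_death.png"))
    plot_funnel(flagged[flagged$kind == "late_survival", ],
                file = file.path(out_dir, "funnel_late_survival.png"))

    stage <- "hospital_factors"
    factors <- lapply(c("early_death", "late_survival"), function(oc) {
      lapply(c("log_volume", "academic", "biopsy_fraction"), function(cv) {
        f <- explore_hospital_factors(smry, oc, cv)
        data.frame(outcome = oc, covariate = cv, slope = f$slope,
                   se = f$se_slope, p = f$p)
      })
    })
    factors <- do.call(rbind, unlist(factors, recursive = FALSE))
    write.csv(factors, file.path(out_dir, "hospital_factors.csv"), row.names = FALSE)

    stage <- "kaplan_meier"
    km <- kaplan_meier(cc$records)
    plot_km(km, file = file.path(out_dir, "km.png"))
    write.csv(km$medians, file.path(out_dir, "km_medians.csv"), row.names = FALSE)
    plot_observed_vs_expected(fit, cc$records,
                              file = file.path(out_dir, "observed_vs_expected.png"))

    logline("pipeline complete")
    list(records = records, truth = truth, summary = smry, fit = fit,
         ratios = flagged, factors = factors, km = km, out_dir = out_dir)
  }, error = function(e) {
    logline("ABORT at stage %s: %s", stage, conditionMessage(e))
    stop(sprintf("pipeline aborted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
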