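#' Poisson funnel control limits for an O/E ratio
#'
#' Prediction limits for the observed count under `Poisson(expected)`,
#' expressed on the ratio (count / expected) scale.
#'
#' `method = "exact"` uses integer Poisson quantiles: the lower count limit is
#' the largest `c` with `P(X < c) <= alpha/2` and the upper the smallest `c`
#' with `P(X > c) <= alpha/2`, so flagging by strict exceedance keeps the
#' false-alarm probability at or below `alpha` by construction (coverage
#' conservative, limits jagged in `expected`).
#'
#' `method = "interpolated"` (default) uses the smooth gamma-quantile
#' interpolation `lower = qgamma(alpha/2, E)/E`,
#' `upper = qgamma(1 - alpha/2, E + 1)/E` (the continuous bridge between
#' adjacent Poisson CDF steps). The curves narrow monotonically in `E`,
#' approach nominal coverage for moderate expected counts, and remain
#' strictly positive at small `E` — which is what allows a hospital with 0
#' observed events and expected counts below ~1 to fall outside the lower
#' limit, at the price of anti-conservative coverage there.
#'
#' @param expected Positive expected event count(s).
#' @param level 95 or 99 (other levels only with `strict_levels = FALSE`).
#' @param method "interpolated" or "exact".
#' @param strict_levels Enforce the conventional 95/99 pair.
#' @return Data frame: expected, lower, upper, level, method.
#' @export
poisson_limits <- function(expected, level = 95,
                           method = c("interpolated", "exact"),
                           strict_levels = TRUE) {
  method <- match.arg(method)
  stopifnot(all(expected > 0))
  if (strict_levels && !level %in% c(95, 99)) {
    stop("level must be 95 or 99 (set strict_levels = FALSE to override)")
  }
  a2 <- (1 - level / 100) / 2
  if (method == "exact") {
    # largest c with P(X <= c - 1) <= a2  <=>  smallest c with F(c) > a2
    lower <- qpois(a2, expected)
    adj <- ppois(lower, expected) <= a2
    lower[adj] <- lower[adj] + 1
    upper <- qpois(1 - a2, expected)
  } else {
    lower <- qgamma(a2, shape = expected)
    upper <- qgamma(1 - a2, shape = expected + 1)
  }
  data.frame(expected = expected, lower = lower / expected,
             upper = upper / expected, level = level, method = method)
}

#' Funnel control-limit curves over a precision grid
#'
#' Limits at 200 log-spaced expected-event values from 0.5 to 1.2 times the
#' maximum expected count, for drawing funnels.
#'
#' @param max_expected Largest expected count among hospitals.
#' @param levels Levels to draw (default 95 and 99).
#' @param method Passed to [poisson_limits()].
#' @param grid_n Grid size.
#' @return A `funnel_limits` data frame of stacked level curves.
#' @export
funnel_limits <- function(max_expected, levels = c(95, 99),
                          method = "interpolated", grid_n = 200) {
  grid <- exp(seq(log(0.5), log(1.2 * max_expected), length.out = grid_n))
  out <- do.call(rbind, lapply(levels, function(l) {
    poisson_limits(grid, l, method)
  }))
  class(out) <- c("funnel_limits", "data.frame")
  out
}

#' Flag hospitals outside funnel control limits
#'
#' Strict exceedance: a ratio exactly on a limit is "within". Direction
#' follows the outcome's interpretation — for early mortality a low ratio is
#' better than expected, for late survival a low ratio is worse.
#'
#' @param ratios A `standardized_ratio` data frame ([oe_ratios()]).
#' @param method Limit method, recorded in the output.
#' @param levels Flag levels, checked from the widest inward.
#' @return `ratios` with `flag` (within/outside_95/outside_99), `direction`
#'   (better/worse) and `method` filled in.
#' @export
flag_outliers <- function(ratios, method = "interpolated", levels = c(95, 99)) {
  stopifnot(all(ratios$expected > 0))
  ratios$flag <- "within"
  ratios$direction <- NA_character_
  for (lv in sort(levels)) {
    lim <- poisson_limits(ratios$expected, lv, method)
    out_low <- ratios$ratio < lim$lower
    out_high <- ratios$ratio > lim$upper
    ratios$flag[out_low | out_high] <- paste0("outside_", lv)
    low_better <- ratios$kind == "early_death"
    ratios$direction[out_low] <- ifelse(low_better[out_low], "better", "worse")
    ratios$direction[out_high] <- ifelse(low_better[out_high], "worse", "better")
  }
  ratios$method <- method
  ratios
}

#' Draw a funnel plot
#'
#' O/E ratios against expected events with 95% (solid) and 99% (dotted)
#' control limits, log-scaled ratio axis; hospitals outside the 95% limits
#' are filled black, better/worse direction colored green/red.
#'
#' @param ratios Flagged `standardized_ratio` rows of one kind.
#' @param method Limit method for the curves.
#' @param file Optional PNG path; NULL draws to the active device.
#' @param main Plot title.
#' @return Invisibly, the limit curves used.
#' @export
plot_funnel <- function(ratios, method = "interpolated", file = NULL,
                        main = unique(ratios$kind)) {
  if (!is.null(file)) {
    png(file, width = 900, height = 700, res = 110)
    on.exit(dev.off())
  }
  lim <- funnel_limits(max(ratios$expected), method = method)
  ylim <- range(c(0.1, 3, ratios$ratio[ratios$ratio > 0]))
  plot(ratios$expected, pmax(ratios$ratio, ylim[1]), log = "y",
       xlim = c(0, max(lim$expected)), ylim = ylim,
       xlab = "Expected number of events", ylab = "Observed / expected ratio",
       main = main, pch = ifelse(ratios$flag == "within", 1, 16),
       col = ifelse(is.na(ratios$direction), "black",
                    ifelse(ratios$direction == "better", "darkgreen", "red")))
  abline(h = 1, col = "grey50")
  for (lv in unique(lim$level)) {
    sub <- lim[lim$level == lv, ]
    lty <- if (lv == 95) 1 else 3
    lines(sub$expected, pmax(sub$lower, ylim[1] / 2), lty = lty)
    lines(sub$expected, sub$upper, lty = lty)
  }
  text(ratios$expected, pmax(ratios$ratio, ylim[1]), ratios$hospital_id,
       pos = 3, cex = 0.8)
  invisible(lim)
}
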