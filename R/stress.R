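#' Detect recovery regions in a steady-state posterior series
#'
#' A recovery region opens at the first point where the steady-state
#' posterior probability drops below `p_low` and tracks the subsequent
#' monotonically increasing stretch; it closes at the first point where
#' the increase breaks, or where the (still increasing) probability
#' exceeds `p_high`. Regions spanning fewer than `min_days` days or
#' containing fewer than `min_points` measurements are discarded (the span
#' threshold is inclusive: a day 10-40 region passes the 30-day rule).
#' Scanning left to right makes regions disjoint and ordered by
#' construction.
#'
#' @param steady_probs Numeric series in `[0, 1]`: posterior probability
#'   of the steady state per grid day.
#' @param grid_times Grid days matching `steady_probs`.
#' @param p_low,p_high Opening/closing thresholds (defaults 0.05, 0.95).
#' @param min_days Minimum region duration in days, exclusive (default 30).
#' @param min_points Minimum number of measurements (default 3).
#' @param animal_id Optional id attached to the regions.
#'
#' @return List of `recovery_region` objects (possibly empty), each with
#'   fields `animal_id`, `start_day`, `end_day`, `days`, `steady_probs`.
#' @export
find_recovery_regions <- function(steady_probs, grid_times,
                                  p_low = 0.05, p_high = 0.95,
                                  min_days = 30, min_points = 3,
                                  animal_id = NA_character_) {
  stopifnot(length(steady_probs) == length(grid_times))
  if (any(steady_probs < 0 | steady_probs > 1, na.rm = TRUE))
    stop("steady_probs must lie in [0, 1]")
  n <- length(steady_probs)
  regions <- list()
  i <- 1
  while (i <= n) {
    if (!is.na(steady_probs[i]) && steady_probs[i] < p_low) {
      j <- i
      # follow the monotone-increasing stretch
      while (j < n && !is.na(steady_probs[j + 1]) &&
             steady_probs[j + 1] > steady_probs[j]) {
        j <- j + 1
        if (steady_probs[j] > p_high) break
      }
      reg <- structure(
        list(animal_id = animal_id, start_day = grid_times[i],
             end_day = grid_times[j], days = grid_times[i:j],
             steady_probs = steady_probs[i:j]),
        class = "recovery_region")
      if (reg$end_day - reg$start_day >= min_days &&
          length(reg$days) >= min_points)
        regions[[length(regions) + 1]] <- reg
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  regions
}

#' Estimate the recovery rate of a region
#'
#' Fits the exponential cumulative distribution function
#' \eqn{1 - e^{-\lambda x}} to the steady-state posterior over the region
#' by least squares, with x measured in days from the region start and
#' \eqn{\lambda} bounded in `[1e-6, 10]` per day. The fitted rate is the
#' adaptation-to-stress measure: larger \eqn{\lambda} means faster return
#' to steady-state homeostasis.
#'
#' @param region A `recovery_region` from [find_recovery_regions()].
#' @param lambda_bounds Search interval for the rate (1/day).
#' @param tol Optimizer tolerance.
#'
#' @return The region with `lambda_hat` and `fit_rss` filled in;
#'   `lambda_hat` is `NA` (fit flagged failed) for a degenerate constant
#'   series.
#' @export
fit_recovery_rate <- function(region, lambda_bounds = c(1e-6, 10),
                              tol = 1e-10) {
  stopifnot(inherits(region, "recovery_region"))
  if (length(region$days) < 3)
    stop("recovery-rate fit needs at least 3 points")
  x <- region$days - region$start_day
  p <- region$steady_probs
  if (length(unique(p)) == 1) {
    region$lambda_hat <- NA_real_
    region$fit_rss <- NA_real_
    region$fit_failed <- TRUE
    return(region)
  }
  obj <- function(lam) sum((p - (1 - exp(-lam * x)))^2)
  # the objective is flat over most of the bounded range (the CDF
  # saturates), so bracket the minimum on a log-spaced grid before the
  # golden-section refinement
  grid <- exp(seq(log(lambda_bounds[1]), log(lambda_bounds[2]),
                  length.out = 80))
  k <- which.min(vapply(grid, obj, numeric(1)))
  lo <- grid[max(k - 1, 1)]
  hi <- grid[min(k + 1, length(grid))]
  opt <- stats::optimize(obj, interval = c(lo, hi), tol = tol)
  region$lambda_hat <- opt$minimum
  region$fit_rss <- opt$objective
  region$fit_failed <- FALSE
  region
}

#' Attribute recovery regions to phenotyping assays and age bins
#'
#' Each region is assigned the most recent assay event preceding its start
#' within `lookback` days (else `"unattributed"`), and an age bin from its
#' start day. Default age bins are (6-18) and (18-30) months at 30
#' days/month.
#'
#' @param regions List of `recovery_region` objects.
#' @param event_schedule Data frame with columns `assay_name`, `age_days`.
#' @param age_bins Named list of `c(start, stop)` day intervals.
#' @param lookback Attribution window in days (default 30).
#'
#' @return The regions with `assay` and `age_bin` fields set.
#' @export
attribute_regions <- function(regions, event_schedule,
                              age_bins = list("6-18mo" = c(180, 540),
                                              "18-30mo" = c(540, 900)),
                              lookback = 30) {
  lapply(regions, function(reg) {
    prior <- event_schedule[event_schedule$age_days <= reg$start_day &
                              event_schedule$age_days >
                                reg$start_day - lookback, , drop = FALSE]
    reg$assay <- if (nrow(prior) > 0)
      prior$assay_name[which.max(prior$age_days)] else "unattributed"
    reg$age_bin <- "other"
    for (b in names(age_bins)) {
      if (reg$start_day >= age_bins[[b]][1] &&
          reg$start_day < age_bins[[b]][2]) {
        reg$age_bin <- b
        break
      }
    }
    reg
  })
}

#' Tabulate fitted recovery regions
#'
#' @param regions List of fitted (and optionally attributed)
#'   `recovery_region` objects.
#'
#' @return Data frame with one row per region.
#' @export
regions_table <- function(regions) {
  if (length(regions) == 0)
    return(data.frame(animal_id = character(0), start_day = numeric(0),
                      end_day = numeric(0), n_points = integer(0),
                      lambda_hat = numeric(0), fit_rss = numeric(0),
                      assay = character(0), age_bin = character(0)))
  out <- do.call(rbind, lapply(regions, function(r) {
    data.frame(animal_id = r$animal_id, start_day = r$start_day,
               end_day = r$end_day, n_points = length(r$days),
               lambda_hat = if (is.null(r$lambda_hat)) NA_real_
               else r$lambda_hat,
               fit_rss = if (is.null(r$fit_rss)) NA_real_ else r$fit_rss,
               assay = if (is.null(r$assay)) NA_character_ else r$assay,
               age_bin = if (is.null(r$age_bin)) NA_character_
               else r$age_bin)
  }))
  rownames(out) <- NULL
  out
}
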