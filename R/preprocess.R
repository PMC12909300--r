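#' Construct a raw body-weight trace
#'
#' A raw trace holds one animal's irregularly sampled body-weight record
#' before gridding: ages in days, weights in grams, diet group, cohort,
#' death day (or censoring), and the schedule of phenotyping events the
#' animal experienced.
#'
#' @param animal_id Character scalar identifying the animal.
#' @param times Numeric vector of ages in days, strictly increasing, >= 0.
#' @param weights Numeric vector of body weights in grams, positive and
#'   finite, same length as `times`.
#' @param diet Diet group, one of `"AL"`, `"1D"`, `"2D"`, `"20"`, `"40"`.
#' @param cohort Character scalar, cohort/generation label.
#' @param death_day Age at death in days, or `NA` if censored.
#' @param censored Logical; `TRUE` if the animal was alive at last contact.
#' @param event_days Numeric vector of phenotyping-event ages in days.
#'
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(animal_id, times, weights,
                      diet = c("AL", "1D", "2D", "20", "40"),
                      cohort = "C1", death_day = NA_real_,
                      censored = is.na(death_day),
                      event_days = numeric(0)) {
  diet <- match.arg(diet)
  times <- as.numeric(times)
  weights <- as.numeric(weights)
  if (length(times) != length(weights))
    stop("times and weights must have equal length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(times < 0)) stop("times must be non-negative")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be finite and positive")
  structure(
    list(animal_id = as.character(animal_id), times = times,
         weights = weights, diet = diet, cohort = as.character(cohort),
         death_day = death_day, censored = isTRUE(censored),
         event_days = as.numeric(event_days)),
    class = "raw_trace"
  )
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace %s: %d measurements, days %g-%g, diet %s>\n",
              x$animal_id, length(x$times),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA, x$diet))
  invisible(x)
}

#' Exclude animals with too few body-weight measurements
#'
#' Animals contributing fewer than `min_measurements` raw weight
#' measurements are dropped from the cohort (the study default excludes
#' animals with fewer than seven). Ordering of the retained traces is
#' preserved and the removals are reported via `attr(, "removed")`.
#'
#' @param traces List of [raw_trace()] objects.
#' @param min_measurements Minimum number of measurements to retain an
#'   animal (default 7; the boundary is inclusive, 7 measurements are kept).
#'
#' @return The retained traces, with attribute `removed` holding the
#'   excluded animal ids.
#' @export
filter_cohort <- function(traces, min_measurements = 7) {
  keep <- vapply(traces, function(tr) length(tr$times) >= min_measurements,
                 logical(1))
  removed <- vapply(traces[!keep], `[[`, character(1), "animal_id")
  out <- traces[keep]
  attr(out, "removed") <- removed
  out
}

# nearest multiple of 10, ties (xx5) rounded up
round_to_grid <- function(t, step = 10) floor(t / step + 0.5) * step

#' Grid a raw trace onto a uniform 10-day sampling interval
#'
#' Measurement ages are rounded to the nearest multiple of 10 days (ties,
#' e.g. day 15, round up). Multiple measurements landing on the same grid
#' day are averaged. Interior grid days with no measurement are filled by
#' one-dimensional linear interpolation between the nearest flanking
#' observed grid points and flagged in `interpolated_mask`. The grid spans
#' from the first to the last observed grid day only; no extrapolation.
#'
#' @param raw A [raw_trace()].
#' @param step Grid step in days (default 10).
#' @param intervention_day Age in days at which the dietary intervention
#'   begins (default 180, i.e. 6 months at 30 days/month).
#'
#' @return An object of class `gridded_trace` with fields `animal_id`,
#'   `grid_times`, `weights`, `interpolated_mask`, `diet`, `cohort`,
#'   `intervention_day`, `death_day`, `censored`, `event_days`.
#' @export
grid_trace <- function(raw, step = 10, intervention_day = 180) {
  stopifnot(inherits(raw, "raw_trace"))
  if (length(raw$times) < 2)
    stop("cannot grid a trace with fewer than 2 measurements")
  g <- round_to_grid(raw$times, step)
  w <- tapply(raw$weights, g, mean)
  occ_times <- as.numeric(names(w))
  ord <- order(occ_times)
  occ_times <- occ_times[ord]
  w <- as.numeric(w)[ord]
  if (length(occ_times) == 1) {
    # all measurements collide on one grid day: their average stands alone
    grid_times <- occ_times
    weights <- w
    mask <- FALSE
  } else {
    grid_times <- seq(occ_times[1], occ_times[length(occ_times)],
                      by = step)
    weights <- stats::approx(occ_times, w, xout = grid_times,
                             method = "linear")$y
    mask <- !(grid_times %in% occ_times)
  }
  structure(
    list(animal_id = raw$animal_id, grid_times = grid_times,
         weights = weights, interpolated_mask = mask, diet = raw$diet,
         cohort = raw$cohort, intervention_day = intervention_day,
         death_day = raw$death_day, censored = raw$censored,
         event_days = raw$event_days),
    class = "gridded_trace"
  )
}

#' @export
print.gridded_trace <- function(x, ...) {
  cat(sprintf(
    "<gridded_trace %s: days %g-%g (%d points, %.1f%% interpolated), diet %s>\n",
    x$animal_id, x$grid_times[1], x$grid_times[length(x$grid_times)],
    length(x$grid_times), 100 * mean(x$interpolated_mask), x$diet))
  invisible(x)
}

# slice a gridded trace to the grid indices in `idx`, keeping metadata
slice_trace <- function(trace, idx) {
  out <- trace
  out$grid_times <- trace$grid_times[idx]
  out$weights <- trace$weights[idx]
  out$interpolated_mask <- trace$interpolated_mask[idx]
  out
}

#' Split a gridded trace at the dietary-intervention boundary
#'
#' The pre-intervention phase covers grid days strictly before
#' `intervention_day`; the post phase covers days at or after it. The two
#' slices partition the trace. An empty side is returned as a zero-length
#' slice with attribute `empty = TRUE`.
#'
#' @param trace A [grid_trace()] result.
#'
#' @return A list with elements `pre` and `post`, each a `gridded_trace`.
#' @export
split_phases <- function(trace) {
  stopifnot(inherits(trace, "gridded_trace"))
  pre_idx <- which(trace$grid_times < trace$intervention_day)
  post_idx <- which(trace$grid_times >= trace$intervention_day)
  pre <- slice_trace(trace, pre_idx)
  post <- slice_trace(trace, post_idx)
  if (length(pre_idx) == 0) attr(pre, "empty") <- TRUE
  if (length(post_idx) == 0) attr(post, "empty") <- TRUE
  list(pre = pre, post = post)
}

#' Read raw traces from a delimited file
#'
#' Expects long-format columns `animal_id`, `age_days`, `weight_g`, `diet`,
#' `cohort`, `death_day`, `censored`; an optional events table supplies
#' `animal_id` (or `cohort`), `assay_name`, `age_days`.
#'
#' @param path Path to the CSV of weight records.
#' @param events_path Optional path to the phenotyping-event schedule CSV.
#'
#' @return A list of [raw_trace()] objects.
#' @export
read_traces <- function(path, events_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ev <- if (!is.null(events_path))
    utils::read.csv(events_path, stringsAsFactors = FALSE) else NULL
  lapply(split(df, df$animal_id), function(d) {
    d <- d[order(d$age_days), ]
    edays <- numeric(0)
    if (!is.null(ev)) {
      if ("animal_id" %in% names(ev))
        edays <- ev$age_days[ev$animal_id == d$animal_id[1]]
      else if ("cohort" %in% names(ev))
        edays <- ev$age_days[ev$cohort == d$cohort[1]]
    }
    raw_trace(d$animal_id[1], d$age_days, d$weight_g, diet = d$diet[1],
              cohort = d$cohort[1], death_day = d$death_day[1],
              censored = as.logical(d$censored[1]), event_days = sort(edays))
  })
}

#' Write gridded traces as a tidy table
#'
#' @param traces List of `gridded_trace` objects.
#' @param path Output CSV path; when `NULL` the data frame is returned
#'   without writing.
#'
#' @return (Invisibly) the tidy data frame with columns `animal_id`,
#'   `grid_day`, `weight_g`, `interpolated`.
#' @export
write_gridded <- function(traces, path = NULL) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(animal_id = tr$animal_id, grid_day = tr$grid_times,
               weight_g = tr$weights, interpolated = tr$interpolated_mask)
  }))
  rownames(df) <- NULL
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
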