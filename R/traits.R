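#' Posterior-weighted state occupancy over a window
#'
#' Occupancy of state s is the mean posterior probability of s over the
#' steps falling in the window, i.e. the (uncertainty-weighted) fraction of
#' time spent in that state.
#'
#' @param posterior A `posterior_states` object (see [forward_backward()]).
#' @param window Length-2 numeric, closed-open day interval `[start, stop)`;
#'   `NULL` uses the whole trace.
#'
#' @return Named numeric vector of per-state fractions (sums to 1), or all
#'   `NA` when the window contains no steps.
#' @export
state_occupancy <- function(posterior, window = NULL) {
  idx <- window_steps(posterior, window)
  K <- ncol(posterior$gamma)
  out <- if (length(idx) == 0) rep(NA_real_, K)
  else colMeans(posterior$gamma[idx, , drop = FALSE])
  names(out) <- posterior_labels(posterior)
  out
}

posterior_labels <- function(posterior) {
  if (!is.null(posterior$state_labels)) posterior$state_labels
  else paste0("state", seq_len(ncol(posterior$gamma)))
}

window_steps <- function(posterior, window) {
  if (is.null(window)) return(seq_along(posterior$step_times))
  which(posterior$step_times >= window[1] & posterior$step_times < window[2])
}

#' Empirical state-transition frequencies over a window
#'
#' Posterior-weighted transition frequencies: entry (i, j) is the summed
#' pairwise marginal \eqn{\xi_t(i, j)} over steps in the window, normalised
#' so each occupied row sums to 1. With hard (0/1) posteriors this equals
#' the count-based transition frequency of the MAP path. Rows for states
#' never occupied in the window are `NA`.
#'
#' @inheritParams state_occupancy
#' @param method `"posterior"` (weighted, default) or `"map"` (counts from
#'   the MAP path).
#'
#' @return K x K matrix of row-normalised transition frequencies.
#' @export
transition_frequencies <- function(posterior, window = NULL,
                                   method = c("posterior", "map")) {
  method <- match.arg(method)
  idx <- window_steps(posterior, window)
  K <- ncol(posterior$gamma)
  labs <- posterior_labels(posterior)
  n_steps <- length(posterior$step_times)
  # transitions from step t to t+1, both inside the window
  tt <- idx[idx < n_steps & (idx + 1) %in% idx]
  counts <- matrix(0, K, K, dimnames = list(labs, labs))
  if (length(tt) > 0) {
    if (method == "posterior") {
      for (t in tt) counts <- counts + posterior$xi[t, , ]
    } else {
      for (t in tt) {
        i <- posterior$map_path[t]
        j <- posterior$map_path[t + 1]
        counts[i, j] <- counts[i, j] + 1
      }
    }
  }
  rs <- rowSums(counts)
  out <- counts / rs
  out[rs == 0, ] <- NA_real_
  out
}

#' Longest continuous bout in a state
#'
#' Length and onset of the longest uninterrupted run of the given state in
#' the MAP path. A run of n steps spans n x 10 days; the start is the grid
#' day of the run's first step. Equal-length runs resolve to the earliest.
#'
#' @param map_path Integer vector of decoded state indices per step.
#' @param step_times Grid days (right endpoints) of the steps.
#' @param state State index to scan for.
#'
#' @return List with `duration` (days) and `start` (day; `NA` and duration
#'   0 when the state never occurs).
#' @export
longest_bout <- function(map_path, step_times, state) {
  stopifnot(length(map_path) == length(step_times))
  r <- rle(map_path == state)
  if (!any(r$values)) return(list(duration = 0, start = NA_real_))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]  # ties: earliest
  step <- if (length(step_times) > 1) diff(step_times[1:2]) else 10
  list(duration = r$lengths[best] * step,
       start = step_times[starts[best]])
}

#' Maximum absolute rate of weight change in a state
#'
#' Over the steps decoded into the given state, the largest absolute
#' weight increment converted to grams/week (a 10-day step scales by
#' 7/10). The normalised variant divides by the body weight at the step's
#' right endpoint — the weight at the time the maximum rate was recorded —
#' giving a fraction of body weight per week.
#'
#' @param trace A `gridded_trace`.
#' @param map_path Decoded state indices per step of `trace`.
#' @param state State index.
#' @param normalize Logical; divide by body weight at the maximising step.
#'
#' @return List with `rate` (g/week, or fraction of body weight/week) and
#'   `day` (grid day of the maximising step); both `NA` when the state
#'   never occurs.
#' @export
max_rate <- function(trace, map_path, state, normalize = FALSE) {
  d <- trace_diffs(trace)
  stopifnot(length(map_path) == length(d))
  idx <- which(map_path == state)
  if (length(idx) == 0) return(list(rate = NA_real_, day = NA_real_))
  step <- diff(trace$grid_times[1:2])
  rates <- abs(d[idx]) * 7 / step
  k <- which.max(rates)
  day <- trace$grid_times[idx[k] + 1]
  rate <- rates[k]
  if (normalize) rate <- rate / trace$weights[idx[k] + 1]
  list(rate = rate, day = day)
}

#' Age-binned and life-fraction-binned homeostasis
#'
#' Occupancy and state stability per time bin. `"age_6mo"` uses 6-month
#' (180-day) non-overlapping bins from birth to 42 months (1260 days);
#' `"life_decile"` splits `[0, death_day)` into ten equal bins of
#' proportion of life lived (censored animals are skipped with a warning).
#' Stability of state s in a bin is the empirical probability of not
#' transitioning out of s:
#' \eqn{\sum_t \xi_t(s, s) / \sum_t \gamma_t(s)} over the bin's steps.
#' Bins with no observations carry `NA`, never zeros.
#'
#' @inheritParams state_occupancy
#' @param trace The `gridded_trace` the posterior was decoded from.
#' @param mode `"age_6mo"` or `"life_decile"`.
#'
#' @return Long data frame: `animal_id`, `bin_mode`, `bin_index`,
#'   `bin_start`, `bin_end`, `state`, `occupancy`, `stability`.
#' @export
binned_homeostasis <- function(posterior, trace,
                               mode = c("age_6mo", "life_decile")) {
  mode <- match.arg(mode)
  if (mode == "age_6mo") {
    edges <- seq(0, 1260, by = 180)
  } else {
    if (is.na(trace$death_day) || isTRUE(trace$censored)) {
      warning("life_decile bins need an observed death day; skipping ",
              trace$animal_id)
      return(NULL)
    }
    edges <- seq(0, trace$death_day, length.out = 11)
  }
  K <- ncol(posterior$gamma)
  labs <- posterior_labels(posterior)
  n_steps <- length(posterior$step_times)
  out <- list()
  for (b in seq_len(length(edges) - 1)) {
    win <- c(edges[b], edges[b + 1])
    idx <- window_steps(posterior, win)
    occ <- state_occupancy(posterior, win)
    stab <- rep(NA_real_, K)
    tt <- idx[idx < n_steps & (idx + 1) %in% idx]
    if (length(tt) > 0) {
      num <- den <- numeric(K)
      for (t in tt) {
        num <- num + diag(matrix(posterior$xi[t, , ], K, K))
        den <- den + posterior$gamma[t, ]
      }
      stab <- ifelse(den > 0, num / den, NA_real_)
    }
    out[[b]] <- data.frame(
      animal_id = trace$animal_id, bin_mode = mode, bin_index = b,
      bin_start = win[1], bin_end = win[2], state = labs,
      occupancy = as.numeric(occ), stability = stab)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

phase_windows <- function(trace) {
  list(pre = c(trace$grid_times[1], trace$intervention_day),
       post = c(trace$intervention_day,
                trace$grid_times[length(trace$grid_times)] + 1))
}

#' Per-animal, per-phase catalog of body-weight-derived traits
#'
#' For each animal and each phase (pre/post intervention) the catalog
#' holds: 3 state occupancies, 9 transition frequencies (including
#' self-transitions), 3 longest-bout durations, 3 bout onset days, and the
#' 2 maximum absolute rates (growth and decline) — 20 scalar traits —
#' plus, when `normalized = TRUE`, auxiliary lifespan- and
#' weight-normalised variants. Occupancies and transitions are
#' posterior-weighted; bouts and rates use the MAP path. Phases with fewer
#' than 3 grid points yield all-`NA` rows.
#'
#' @param fit An [fit_arhmm()] result with K = 3.
#' @param traces List of `gridded_trace` objects.
#' @param drop Character vector of trait column names to omit (the study
#'   catalog has 19 members; the default emits all 20).
#' @param normalized Include normalised auxiliary columns.
#'
#' @return Data frame, one row per animal x phase.
#' @export
trait_table <- function(fit, traces, drop = character(0),
                        normalized = TRUE) {
  labs <- fit$state_labels
  K <- fit$params$K
  rows <- list()
  for (tr in traces) {
    ps <- forward_backward(fit$params, tr)
    wins <- phase_windows(tr)
    lifespan <- if (!is.na(tr$death_day)) tr$death_day
    else tr$grid_times[length(tr$grid_times)]
    for (phase in names(wins)) {
      win <- wins[[phase]]
      idx <- window_steps(ps, win)
      row <- list(animal_id = tr$animal_id, phase = phase, diet = tr$diet)
      n_grid <- length(idx) + (length(idx) > 0)  # steps + left anchor point
      if (n_grid < 3) {
        rows[[length(rows) + 1]] <- c(row, empty_traits(labs, normalized))
        next
      }
      occ <- state_occupancy(ps, win)
      for (s in seq_len(K)) row[[paste0("occ_", labs[s])]] <- occ[[s]]
      tf <- transition_frequencies(ps, win)
      for (i in seq_len(K)) for (j in seq_len(K))
        row[[paste0("trans_", labs[i], "_", labs[j])]] <- tf[i, j]
      sub_path <- ps$map_path[idx]
      sub_times <- ps$step_times[idx]
      phase_dur <- length(idx) * 10
      for (s in seq_len(K)) {
        lb <- longest_bout(sub_path, sub_times, s)
        row[[paste0("bout_", labs[s])]] <- lb$duration
        row[[paste0("bout_start_", labs[s])]] <- lb$start
        if (normalized) {
          row[[paste0("bout_norm_", labs[s])]] <- lb$duration / phase_dur
          row[[paste0("bout_start_norm_", labs[s])]] <-
            if (is.na(lb$start)) NA_real_ else lb$start / lifespan
        }
      }
      for (s in which(labs %in% c("growth", "decline"))) {
        full_path <- ps$map_path
        full_path[-idx] <- NA_integer_
        mr <- max_rate(tr, full_path, s)
        row[[paste0("max_rate_", labs[s])]] <- mr$rate
        if (normalized) {
          mrn <- max_rate(tr, full_path, s, normalize = TRUE)
          row[[paste0("max_rate_norm_", labs[s])]] <- mrn$rate
          row[[paste0("rate_time_", labs[s])]] <- mr$day
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  if (length(drop) > 0) out <- out[, setdiff(names(out), drop), drop = FALSE]
  out
}

empty_traits <- function(labs, normalized) {
  nm <- c(paste0("occ_", labs),
          as.vector(outer(labs, labs, function(i, j)
            paste0("trans_", i, "_", j))),
          paste0("bout_", labs), paste0("bout_start_", labs))
  if (normalized)
    nm <- c(nm, paste0("bout_norm_", labs), paste0("bout_start_norm_", labs))
  nm <- c(nm, paste0("max_rate_", intersect(c("growth", "decline"), labs)))
  if (normalized)
    nm <- c(nm, paste0("max_rate_norm_",
                       intersect(c("growth", "decline"), labs)),
            paste0("rate_time_", intersect(c("growth", "decline"), labs)))
  stats::setNames(as.list(rep(NA_real_, length(nm))), nm)
}
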