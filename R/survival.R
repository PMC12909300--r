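#' Default post-intervention age bins
#'
#' Six contiguous 180-day bins spanning 180 to 1260 days of age.
#'
#' @param from,to,by Bin range and width in days.
#' @return List of `c(start, stop)` closed-open intervals.
#' @export
default_age_bins <- function(from = 180, to = 1260, by = 180) {
  edges <- seq(from, to, by = by)
  lapply(seq_len(length(edges) - 1), function(i) c(edges[i], edges[i + 1]))
}

#' Build a start-stop episode table with bin-gated covariates
#'
#' Converts gridded traces (and optionally per-bin trait values) into the
#' long-format counting-process rows a time-varying proportional-hazards
#' fit expects. Episodes are split at every grid measurement time and
#' every bin boundary. Within age bin j, the bin-j trait covariate carries
#' the animal's bin-j value and every other bin's trait covariate is 0;
#' bin-gated body weight carries the current measured weight inside bin j
#' and 0 outside; optional interactions multiply the gated weight by diet
#' dummies (AL is the reference diet). Death closes the final episode with
#' `event = 1`; censoring with `event = 0`.
#'
#' @param traces List of `gridded_trace` objects.
#' @param trait_values Optional data frame `animal_id`, `bin_index`,
#'   `value` of the per-bin trait; z-scored across animals within each bin
#'   when `zscore_traits` is `TRUE`. Missing combinations are gated to 0.
#' @param bins List of `c(start, stop)` day intervals
#'   (default [default_age_bins()]).
#' @param include_bw Include bin-gated body weight covariates.
#' @param include_bw_diet Include bin-gated body-weight x diet columns.
#' @param zscore_traits Standardise trait values per bin.
#' @param weight_center,weight_scale Centering/scaling for body weight
#'   (grams); defaults 30 and 5.
#'
#' @return Data frame of episodes with attribute `covariates` naming the
#'   model columns.
#' @export
build_episodes <- function(traces, trait_values = NULL,
                           bins = default_age_bins(),
                           include_bw = TRUE, include_bw_diet = FALSE,
                           zscore_traits = TRUE,
                           weight_center = 30, weight_scale = 5) {
  n_bins <- length(bins)
  bin_edges <- c(vapply(bins, `[`, numeric(1), 1),
                 bins[[n_bins]][2])
  if (!is.null(trait_values) && zscore_traits) {
    trait_values <- do.call(rbind, lapply(
      split(trait_values, trait_values$bin_index), function(d) {
        mu <- mean(d$value, na.rm = TRUE)
        sg <- stats::sd(d$value, na.rm = TRUE)
        d$value <- if (is.finite(sg) && sg > 0) (d$value - mu) / sg else 0
        d
      }))
  }
  diets <- sort(unique(vapply(traces, `[[`, character(1), "diet")))
  diet_levels <- setdiff(diets, "AL")
  cohorts <- sort(unique(vapply(traces, `[[`, character(1), "cohort")))
  cohort_levels <- if (length(cohorts) > 1) cohorts[-1] else character(0)
  rows <- list()
  skipped <- character(0)
  for (tr in traces) {
    entry <- max(tr$grid_times[1], bin_edges[1])
    exit <- if (!is.na(tr$death_day)) tr$death_day
    else tr$grid_times[length(tr$grid_times)]
    exit <- min(exit, bin_edges[n_bins + 1])
    if (exit <= entry) {
      skipped <- c(skipped, tr$animal_id)
      next
    }
    cuts <- sort(unique(c(entry, exit,
                          tr$grid_times[tr$grid_times > entry &
                                          tr$grid_times < exit],
                          bin_edges[bin_edges > entry & bin_edges < exit])))
    died <- !is.na(tr$death_day) && !isTRUE(tr$censored) &&
      tr$death_day <= bin_edges[n_bins + 1]
    for (e in seq_len(length(cuts) - 1)) {
      start <- cuts[e]
      stop_ <- cuts[e + 1]
      bin_j <- findInterval(start, bin_edges, rightmost.closed = FALSE)
      bin_j <- min(max(bin_j, 1), n_bins)
      # current weight: last measurement at or before episode start
      w_idx <- max(which(tr$grid_times <= start))
      bw <- (tr$weights[w_idx] - weight_center) / weight_scale
      row <- list(animal_id = tr$animal_id, start = start, stop = stop_,
                  event = as.integer(died && e == length(cuts) - 1))
      for (d in diet_levels)
        row[[paste0("diet_", d)]] <- as.numeric(tr$diet == d)
      for (g in cohort_levels)
        row[[paste0("cohort_", g)]] <- as.numeric(tr$cohort == g)
      if (!is.null(trait_values)) {
        for (j in seq_len(n_bins)) {
          v <- 0
          if (j == bin_j) {
            hit <- trait_values$value[
              trait_values$animal_id == tr$animal_id &
                trait_values$bin_index == j]
            if (length(hit) == 1 && is.finite(hit)) v <- hit
          }
          row[[paste0("trait_bin", j)]] <- v
        }
      }
      if (include_bw) {
        for (j in seq_len(n_bins))
          row[[paste0("bw_bin", j)]] <- if (j == bin_j) bw else 0
      }
      if (include_bw_diet) {
        for (j in seq_len(n_bins)) for (d in diet_levels)
          row[[paste0("bw_bin", j, "_diet_", d)]] <-
            if (j == bin_j) bw * as.numeric(tr$diet == d) else 0
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  if (length(rows) == 0) stop("no animals with post-intervention data")
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  if (length(skipped) > 0)
    warning("excluded animals with no post-intervention observation: ",
            paste(skipped, collapse = ", "))
  attr(out, "covariates") <- setdiff(names(out),
                                     c("animal_id", "start", "stop",
                                       "event"))
  out
}

#' Fit the time-varying proportional-hazards model
#'
#' Maximises the (optionally L2-penalised) Cox partial likelihood on
#' start-stop episode data with Efron tie handling, via
#' [survival::coxph()]. Returns per-covariate log proportional hazards,
#' standard errors from the information matrix, two-sided Wald p-values,
#' and the concordance index on the fitting data.
#'
#' @param episodes Episode table from [build_episodes()] (or any data
#'   frame with `start`, `stop`, `event` and covariate columns).
#' @param penalty Ridge strength (coefficient of the squared-norm penalty);
#'   0 for an unpenalised fit.
#' @param covariates Covariate column names; defaults to the table's
#'   `covariates` attribute.
#'
#' @return Object of class `tv_cox_fit`: data frame `coefficients`
#'   (`term`, `beta`, `se`, `wald_p`), `c_index`, `penalty`, and the
#'   underlying `coxph` fit.
#' @export
fit_tv_cox <- function(episodes, penalty = 0, covariates = NULL) {
  if (is.null(covariates)) covariates <- attr(episodes, "covariates")
  if (is.null(covariates))
    covariates <- setdiff(names(episodes),
                          c("animal_id", "start", "stop", "event"))
  if (sum(episodes$event) == 0) stop("no events in episode table")
  keep <- vapply(covariates, function(v)
    stats::sd(episodes[[v]]) > 0, logical(1))
  dropped <- covariates[!keep]
  covariates <- covariates[keep]
  rhs <- if (penalty > 0)
    sprintf("ridge(%s, theta = %g, scale = FALSE)",
            paste(covariates, collapse = ", "), penalty)
  else paste(covariates, collapse = " + ")
  fml <- stats::as.formula(paste("Surv(start, stop, event) ~", rhs))
  fit <- survival::coxph(fml, data = episodes, ties = "efron")
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  term <- covariates[seq_along(beta)]
  wald_p <- 2 * stats::pnorm(-abs(beta / se))
  conc <- survival::concordance(fit)
  structure(
    list(coefficients = data.frame(term = term, beta = as.numeric(beta),
                                   se = as.numeric(se),
                                   wald_p = as.numeric(wald_p)),
         c_index = as.numeric(conc$concordance), penalty = penalty,
         dropped = dropped, coxph = fit),
    class = "tv_cox_fit")
}

#' @export
print.tv_cox_fit <- function(x, ...) {
  cat(sprintf("<tv_cox_fit: %d covariates, penalty %g, C-index %.3f>\n",
              nrow(x$coefficients), x$penalty, x$c_index))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Interpret a log proportional hazard
#'
#' Translates an effect size on the log-hazard scale into the hazard
#' ratio \eqn{e^\beta} and the per-unit percentage change in
#' instantaneous mortality risk \eqn{100 (e^\beta - 1)}; e.g. a log
#' proportional hazard of 0.065 corresponds to a hazard ratio of about
#' 1.0671, a 6.7% higher risk of death per unit of the covariate.
#'
#' @param beta Log proportional hazard.
#' @return List with `hazard_ratio` and `pct_change`.
#' @export
hazard_interpretation <- function(beta) {
  list(hazard_ratio = exp(beta), pct_change = 100 * (exp(beta) - 1))
}

#' Choose the ridge penalty by held-out concordance
#'
#' Animals (not episodes) are split into training and validation sets;
#' each candidate penalty is fitted on the training episodes and scored by
#' the concordance index of its linear predictor on the validation
#' episodes. The penalty with the highest validation C-index wins; ties go
#' to the smaller penalty. A validation split with no events is redrawn
#' with an incremented seed.
#'
#' @param episodes Episode table from [build_episodes()].
#' @param grid Numeric vector of candidate penalties.
#' @param split_frac Training fraction (default 0.8).
#' @param seed Integer seed for the split.
#'
#' @return List with `best_penalty`, `c_index` (named per penalty), and
#'   the `seed` actually used.
#' @export
select_penalty <- function(episodes, grid = c(0.01, 0.1, 1, 10),
                           split_frac = 0.8, seed = 1) {
  if (length(grid) == 0) stop("penalty grid must be non-empty")
  grid <- sort(grid)  # ties resolve to the smaller penalty
  covariates <- attr(episodes, "covariates")
  ids <- unique(episodes$animal_id)
  for (attempt in 0:20) {
    set.seed(seed + attempt)
    train_ids <- sample(ids, max(1, round(split_frac * length(ids))))
    tr_ep <- episodes[episodes$animal_id %in% train_ids, ]
    va_ep <- episodes[!episodes$animal_id %in% train_ids, ]
    if (sum(tr_ep$event) > 0 && sum(va_ep$event) > 0) break
  }
  if (sum(va_ep$event) == 0)
    stop("could not find a validation split with events")
  used_seed <- seed + attempt
  attr(tr_ep, "covariates") <- covariates
  cidx <- stats::setNames(numeric(length(grid)), grid)
  for (i in seq_along(grid)) {
    fit <- fit_tv_cox(tr_ep, penalty = grid[i], covariates = covariates)
    terms <- fit$coefficients$term
    lp <- as.matrix(va_ep[, terms, drop = FALSE]) %*%
      fit$coefficients$beta
    cidx[i] <- as.numeric(survival::concordance(
      Surv(start, stop, event) ~ lp,
      data = cbind(va_ep, lp = as.numeric(lp)),
      reverse = TRUE)$concordance)
  }
  best <- grid[which.max(cidx)]  # which.max breaks ties by first = smallest
  list(best_penalty = best, c_index = cidx, seed = used_seed)
}
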