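#' Configuration for the synthetic-cohort generator
#'
#' The generator mirrors the statistical structure of the study design:
#' 10-day-sampled body-weight traces from around 60 to at most 1260 days
#' of life, a dietary intervention at 180 days switching the latent-state
#' transition dynamics by diet group, annual phenotyping events that force
#' decline bouts followed by a return to steady state at a diet-specific
#' rate, death times whose hazard depends on decline-state occupancy, and
#' founder-dosage genotypes with an optional planted effect on a derived
#' trait.
#'
#' Default state intercepts echo the scale of the fitted states (growth
#' about +0.5 g per 10-day step, steady about 0, decline about -0.8); the
#' diet-specific transition matrices make calorie-restricted groups
#' stickier in steady state. These are simulation defaults that define the
#' test conditions, not estimates.
#'
#' @param n_animals Number of animals.
#' @param diets Diet labels.
#' @param diet_props Sampling proportions per diet (sum to 1).
#' @param start_day First grid day (default 60).
#' @param step Grid step in days (10).
#' @param intervention_day Diet switch day (180).
#' @param max_age Administrative censoring age in days (1260).
#' @param eta0 True state intercept means, ordered growth/steady/decline.
#' @param sigma0_sq True intercept variances.
#' @param sigma_sq True noise variances.
#' @param pi0 Initial state distribution.
#' @param sticky_pre Diagonal of the shared pre-intervention transition
#'   matrix.
#' @param sticky_post Named per-diet diagonal of the post-intervention
#'   steady row (steadier diets hold steady longer).
#' @param event_days Phenotyping-event start days (annual blocks).
#' @param lambda_by_diet True recovery rate (1/day) per diet governing how
#'   fast a forced decline bout ends.
#' @param base_hazard Baseline death hazard per day.
#' @param hazard_coef_decline Log-hazard increase per percentage point of
#'   decline occupancy in the current 180-day age bin.
#' @param init_weight_mean,init_weight_sd Initial weight (grams) at
#'   `start_day`.
#' @param n_markers,n_founders Genetics block dimensions.
#' @param planted_marker,planted_founder,planted_effect Planted genetic
#'   effect: `planted_effect` trait units per dosage unit of
#'   `planted_founder` at `planted_marker` (0 disables).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_animals = 100,
                       diets = c("AL", "1D", "2D", "20", "40"),
                       diet_props = rep(0.2, 5),
                       start_day = 60, step = 10,
                       intervention_day = 180, max_age = 1260,
                       eta0 = c(0.5, 0, -0.8),
                       sigma0_sq = c(0.0025, 0.0025, 0.0025),
                       sigma_sq = c(0.02, 0.02, 0.02),
                       pi0 = c(0.8, 0.15, 0.05),
                       sticky_pre = 0.9,
                       sticky_post = c(AL = 0.88, `1D` = 0.90, `2D` = 0.91,
                                       `20` = 0.93, `40` = 0.95),
                       event_days = c(300, 660, 1020),
                       lambda_by_diet = c(AL = 0.03, `1D` = 0.04,
                                          `2D` = 0.045, `20` = 0.05,
                                          `40` = 0.06),
                       base_hazard = log(2) / 800,
                       hazard_coef_decline = 0.065,
                       init_weight_mean = 20, init_weight_sd = 2,
                       n_markers = 50, n_founders = 8,
                       planted_marker = 1, planted_founder = 8,
                       planted_effect = 0) {
  stopifnot(abs(sum(diet_props) - 1) < 1e-8,
            length(diets) == length(diet_props),
            all(sigma_sq > 0), all(sigma0_sq >= 0))
  structure(as.list(environment()), class = "sim_config")
}

# transition matrix with given diagonal, remainder spread evenly
sticky_matrix <- function(diag_p, K = 3) {
  A <- matrix((1 - diag_p) / (K - 1), K, K)
  diag(A) <- diag_p
  A
}

# diet-specific post-intervention transition matrix: the steady row gets
# the diet's stickiness, other rows pull toward steady
post_matrix <- function(config, diet) {
  s <- config$sticky_post[[diet]]
  A <- sticky_matrix(0.85)
  A[2, ] <- c((1 - s) / 2, s, (1 - s) / 2)
  # growth and decline return preferentially to steady
  A[1, ] <- c(0.85, 0.12, 0.03)
  A[3, ] <- c(0.03, 0.12, 0.85)
  A
}

#' Simulate one body-weight trace with its true state path
#'
#' States evolve by the pre-intervention Markov chain until the
#' intervention day and by the diet-specific chain afterwards. Each step's
#' weight increment is the state intercept (drawn once per animal and
#' state from its Gaussian) plus observation noise. A phenotyping event
#' forces a decline bout whose per-step end probability is
#' \eqn{1 - e^{-\lambda \cdot step}} with the diet's true recovery rate,
#' after which the chain is returned to steady state.
#'
#' @param config A [sim_config()].
#' @param animal_id Identifier for the simulated animal.
#' @param diet Diet group label.
#' @param seed Integer seed.
#'
#' @return List with `trace` (a `gridded_trace` spanning to `max_age`,
#'   untruncated) and `path` (true state indices per step: 1 growth,
#'   2 steady, 3 decline).
#' @export
simulate_trace <- function(config, animal_id = "sim1", diet = "AL",
                           seed = 1) {
  set.seed(seed)
  grid_times <- seq(config$start_day, config$max_age, by = config$step)
  n_steps <- length(grid_times) - 1
  A_pre <- sticky_matrix(config$sticky_pre)
  A_post <- post_matrix(config, diet)
  phi0 <- stats::rnorm(3, config$eta0, sqrt(config$sigma0_sq))
  lam <- config$lambda_by_diet[[diet]]
  p_end <- 1 - exp(-lam * config$step)
  weights <- numeric(length(grid_times))
  weights[1] <- max(stats::rnorm(1, config$init_weight_mean,
                                 config$init_weight_sd), 5)
  path <- integer(n_steps)
  s <- sample.int(3, 1, prob = config$pi0)
  forced_decline <- FALSE
  for (t in seq_len(n_steps)) {
    day <- grid_times[t + 1]
    if (any(abs(day - config$event_days) < config$step / 2))
      forced_decline <- TRUE
    if (forced_decline) s <- 3L
    path[t] <- s
    inc <- phi0[s] + stats::rnorm(1, 0, sqrt(config$sigma_sq[s]))
    weights[t + 1] <- max(weights[t] + inc, 1)
    # the forced bout lasts at least the trigger step; it ends (into
    # steady state) with the diet's per-step recovery probability
    if (forced_decline && stats::runif(1) < p_end) {
      forced_decline <- FALSE
      s <- 2L
    } else if (!forced_decline) {
      A <- if (day < config$intervention_day) A_pre else A_post
      s <- sample.int(3, 1, prob = A[s, ])
    }
  }
  trace <- structure(
    list(animal_id = animal_id, grid_times = grid_times,
         weights = weights,
         interpolated_mask = rep(FALSE, length(grid_times)), diet = diet,
         cohort = "sim", intervention_day = config$intervention_day,
         death_day = NA_real_, censored = TRUE,
         event_days = config$event_days),
    class = "gridded_trace")
  list(trace = trace, path = path, phi0 = phi0)
}

#' Simulate a death time from state-occupancy features
#'
#' Piecewise-exponential death time: within each 180-day age bin the
#' hazard is \eqn{h_0 \exp(\beta \cdot occ)}, where `occ` is the decline
#' occupancy (percentage points) of that bin. Deaths beyond `max_age` are
#' administratively censored.
#'
#' @param decline_occ_pct Decline occupancy (0-100) per 180-day bin,
#'   starting at day 0.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#'
#' @return List with `death_day` (`NA` when censored) and `censored`.
#' @export
simulate_survival <- function(decline_occ_pct, config, seed = 1) {
  set.seed(seed)
  bin_width <- 180
  t0 <- 0
  for (j in seq_along(decline_occ_pct)) {
    occ <- decline_occ_pct[j]
    if (is.na(occ)) occ <- 0
    h <- config$base_hazard * exp(config$hazard_coef_decline * occ)
    wait <- stats::rexp(1, rate = h)
    if (wait < bin_width) {
      dd <- t0 + wait
      if (dd <= config$max_age)
        return(list(death_day = dd, censored = FALSE))
      break
    }
    t0 <- t0 + bin_width
    if (t0 >= config$max_age) break
  }
  list(death_day = NA_real_, censored = TRUE)
}

#' Simulate founder-of-origin dosage matrices
#'
#' Per marker, a founder frequency vector is drawn from a symmetric
#' Dirichlet; each animal then receives two independent founder draws, so
#' every dosage row is a sum of two indicator vectors and sums to exactly
#' 2 (diploid expected founder-of-origin counts).
#'
#' @param n_animals,n_markers Dimensions.
#' @param seed Integer seed.
#' @param dirichlet_conc Dirichlet concentration (default 2).
#'
#' @return List of markers, each with `marker_id`, `chrom`, `pos_bp`,
#'   `dosages` (animals x 8, rows summing to 2).
#' @export
simulate_founder_genotypes <- function(n_animals, n_markers, seed = 1,
                                       dirichlet_conc = 2) {
  set.seed(seed)
  lapply(seq_len(n_markers), function(m) {
    g <- stats::rgamma(8, dirichlet_conc)
    freq <- g / sum(g)
    draws1 <- sample.int(8, n_animals, replace = TRUE, prob = freq)
    draws2 <- sample.int(8, n_animals, replace = TRUE, prob = freq)
    D <- matrix(0, n_animals, 8, dimnames = list(NULL, DO_FOUNDERS))
    for (i in seq_len(n_animals)) {
      D[i, draws1[i]] <- D[i, draws1[i]] + 1
      D[i, draws2[i]] <- D[i, draws2[i]] + 1
    }
    list(marker_id = sprintf("m%04d", m), chrom = 1L,
         pos_bp = m * 1000000L, dosages = D)
  })
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Draws diets, traces, true state paths, death times (from true decline
#' occupancy), and founder genotypes, with per-animal seed streams derived
#' from the master seed. The returned traces are truncated at death.
#'
#' @param config A [sim_config()].
#' @param seed Master integer seed.
#'
#' @return List with `traces` (gridded, truncated at death),
#'   `ground_truth` (per-animal `path`, `phi0`, `death_day`), `config`,
#'   and `genotypes`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  n <- config$n_animals
  diets <- sample(config$diets, n, replace = TRUE,
                  prob = config$diet_props)
  animal_seeds <- sample.int(.Machine$integer.max - 1, 2 * n)
  traces <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("a%04d", i)
    sim <- simulate_trace(config, id, diets[i], seed = animal_seeds[i])
    # decline occupancy (percentage) per 180-day bin from the true path
    step_days <- sim$trace$grid_times[-1]
    bins <- findInterval(step_days, seq(0, config$max_age, by = 180),
                         rightmost.closed = TRUE)
    occ <- vapply(seq_len(max(bins)), function(b) {
      ix <- bins == b
      if (!any(ix)) return(NA_real_)
      100 * mean(sim$path[ix] == 3)
    }, numeric(1))
    surv <- simulate_survival(occ, config, seed = animal_seeds[n + i])
    tr <- sim$trace
    path <- sim$path
    if (!surv$censored) {
      keep <- tr$grid_times <= surv$death_day
      if (sum(keep) < 3) keep[1:3] <- TRUE
      tr <- slice_trace(tr, which(keep))
      path <- path[seq_len(length(tr$grid_times) - 1)]
      tr$death_day <- surv$death_day
      tr$censored <- FALSE
    } else {
      tr$death_day <- NA_real_
      tr$censored <- TRUE
    }
    traces[[i]] <- tr
    truth[[i]] <- list(animal_id = id, path = path, phi0 = sim$phi0,
                       death_day = tr$death_day, diet = diets[i])
  }
  genotypes <- simulate_founder_genotypes(n, config$n_markers,
                                          seed = seed + 1)
  list(traces = traces, ground_truth = truth, config = config,
       genotypes = genotypes)
}

#' Simulate traces directly from an autoregressive hidden Markov model
#'
#' Clean generative draws (no events, no deaths) used for parameter- and
#' order-recovery studies: states follow the chain of `params`, each
#' animal draws one intercept per state from
#' \eqn{N(\eta_{0s}, \sigma^2_{0s})}, and increments add the state noise.
#'
#' @param params An [arhmm_params()] object (the ground truth).
#' @param n_traces Number of animals.
#' @param n_points Grid points per trace (steps + 1).
#' @param seed Integer seed.
#' @param start_day,step Grid layout (defaults 60 and 10 days).
#' @param init_weight_mean,init_weight_sd Initial weight distribution.
#'
#' @return List with `traces` (gridded) and `paths` (true state indices
#'   per step).
#' @export
simulate_arhmm_traces <- function(params, n_traces, n_points, seed = 1,
                                  start_day = 60, step = 10,
                                  init_weight_mean = 20,
                                  init_weight_sd = 2) {
  set.seed(seed)
  K <- params$K
  grid_times <- seq(start_day, by = step, length.out = n_points)
  traces <- vector("list", n_traces)
  paths <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    phi0 <- stats::rnorm(K, params$eta0, sqrt(params$sigma0_sq))
    w <- numeric(n_points)
    w[1] <- max(stats::rnorm(1, init_weight_mean, init_weight_sd), 5)
    path <- integer(n_points - 1)
    s <- sample.int(K, 1, prob = params$pi0)
    for (t in seq_len(n_points - 1)) {
      path[t] <- s
      w[t + 1] <- w[t] + phi0[s] +
        stats::rnorm(1, 0, sqrt(params$sigma_sq[s]))
      s <- sample.int(K, 1, prob = params$A[s, ])
    }
    traces[[i]] <- structure(
      list(animal_id = sprintf("sim%04d", i), grid_times = grid_times,
           weights = w, interpolated_mask = rep(FALSE, n_points),
           diet = "AL", cohort = "sim", intervention_day = 180,
           death_day = NA_real_, censored = TRUE,
           event_days = numeric(0)),
      class = "gridded_trace")
    paths[[i]] <- path
  }
  list(traces = traces, paths = paths)
}

#' Apply a planted founder effect to a trait vector
#'
#' Adds `effect` x dosage of the configured founder at the planted marker
#' to the trait, producing the ground-truth genetic signal for scan power
#' checks.
#'
#' @param trait Numeric per-animal trait values.
#' @param genotypes Output of [simulate_founder_genotypes()].
#' @param config A [sim_config()] (fields `planted_marker`,
#'   `planted_founder`, `planted_effect`).
#'
#' @return The trait vector with the planted effect added.
#' @export
apply_planted_effect <- function(trait, genotypes, config) {
  if (config$planted_effect == 0) return(trait)
  D <- genotypes[[config$planted_marker]]$dosages
  trait + config$planted_effect * D[, config$planted_founder]
}
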