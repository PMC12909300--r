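# shared fixtures: build traces/posteriors in code, plus the brute-force
# forward-backward oracle used to validate the recursions

make_trace <- function(weights, start_day = 0, step = 10, diet = "AL",
                       animal_id = "t1", intervention_day = 180,
                       death_day = NA_real_, censored = is.na(death_day),
                       event_days = numeric(0)) {
  n <- length(weights)
  structure(
    list(animal_id = animal_id,
         grid_times = seq(start_day, by = step, length.out = n),
         weights = as.numeric(weights),
         interpolated_mask = rep(FALSE, n), diet = diet, cohort = "c1",
         intervention_day = intervention_day, death_day = death_day,
         censored = censored, event_days = event_days),
    class = "gridded_trace")
}

random_params <- function(K = 3, seed = 1) {
  set.seed(seed)
  rdir <- function(n) { g <- stats::rgamma(n, 1); g / sum(g) }
  arhmm_params(rdir(K), t(replicate(K, rdir(K))),
               stats::rnorm(K, 0, 0.5), stats::runif(K, 0, 0.05),
               stats::runif(K, 0.01, 0.1))
}

# exhaustive enumeration over all K^(T-1) state paths
brute_force_posteriors <- function(params, trace) {
  log_e <- emission_stats(params, trace)
  Tm <- nrow(log_e)
  K <- params$K
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tm)))
  lp <- apply(paths, 1, function(s) {
    out <- log(params$pi0[s[1]]) + sum(log_e[cbind(seq_len(Tm), s)])
    if (Tm > 1)
      out <- out + sum(log(params$A[cbind(s[-Tm], s[-1])]))
    out
  })
  Z <- max(lp) + log(sum(exp(lp - max(lp))))
  w <- exp(lp - Z)
  gamma <- vapply(seq_len(K), function(k) colSums(w * (paths == k)),
                  numeric(Tm))
  xi <- array(0, c(max(Tm - 1, 0), K, K))
  if (Tm > 1) {
    for (t in seq_len(Tm - 1)) for (i in seq_len(K)) for (j in seq_len(K))
      xi[t, i, j] <- sum(w[paths[, t] == i & paths[, t + 1] == j])
  }
  list(gamma = matrix(gamma, Tm, K), xi = xi, loglik = Z)
}

# hand-made posterior_states from a hard path (0/1 marginals)
hard_posterior <- function(path, step_times, K = 3,
                           labels = c("growth", "steady", "decline")) {
  Tm <- length(path)
  gamma <- matrix(0, Tm, K)
  gamma[cbind(seq_len(Tm), path)] <- 1
  xi <- array(0, c(Tm - 1, K, K))
  for (t in seq_len(Tm - 1)) xi[t, path[t], path[t + 1]] <- 1
  structure(
    list(gamma = gamma, xi = xi, loglik = 0, map_path = path,
         step_times = step_times, state_labels = labels),
    class = "posterior_states")
}

default_truth <- function() {
  arhmm_params(c(0.8, 0.15, 0.05),
               rbind(c(0.85, 0.12, 0.03),
                     c(0.05, 0.90, 0.05),
                     c(0.03, 0.12, 0.85)),
               c(0.5, 0, -0.8), rep(0, 3), rep(0.0225, 3))
}
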