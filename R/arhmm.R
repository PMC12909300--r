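#' Parameters of the constrained lag-1 autoregressive hidden Markov model
#'
#' The model writes body weight as
#' \eqn{y_t = \phi_0^{s_t} + y_{t-1} + \epsilon_t^{s_t}}: the lag-1
#' autoregressive coefficient is fixed at 1 so that each latent state is
#' characterised purely by the distribution of its weight increment. The
#' state intercept \eqn{\phi_0^{s}} is a Gaussian random variable with mean
#' `eta0[s]` and variance `sigma0_sq[s]`, and the observation noise has
#' variance `sigma_sq[s]`. Latent states follow a first-order Markov chain
#' with initial distribution `pi0` and transition matrix `A`.
#'
#' @param pi0 Initial state distribution (length K, non-negative, sums to 1).
#' @param A K x K transition matrix; `A[i, j]` is P(s_t = j | s_{t-1} = i);
#'   rows sum to 1.
#' @param eta0 Per-state intercept mean, grams per 10-day step.
#' @param sigma0_sq Per-state intercept variance (grams^2), >= 0.
#' @param sigma_sq Per-state noise variance (grams^2), > 0.
#'
#' @return An object of class `arhmm_params`.
#' @export
arhmm_params <- function(pi0, A, eta0, sigma0_sq, sigma_sq) {
  K <- length(pi0)
  A <- matrix(as.numeric(A), K, K)
  stopifnot(length(eta0) == K, length(sigma0_sq) == K, length(sigma_sq) == K)
  if (any(pi0 < 0) || abs(sum(pi0) - 1) > 1e-10)
    stop("pi0 must be a probability distribution")
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-10))
    stop("rows of A must be probability distributions")
  if (any(sigma0_sq < 0)) stop("sigma0_sq must be non-negative")
  if (any(sigma_sq <= 0)) stop("sigma_sq must be positive")
  structure(
    list(K = K, pi0 = as.numeric(pi0), A = A, eta0 = as.numeric(eta0),
         sigma0_sq = as.numeric(sigma0_sq), sigma_sq = as.numeric(sigma_sq),
         phi1 = 1),
    class = "arhmm_params"
  )
}

#' @export
print.arhmm_params <- function(x, ...) {
  cat(sprintf("<arhmm_params: K = %d, phi1 fixed at 1>\n", x$K))
  cat("  eta0      :", signif(x$eta0, 4), "\n")
  cat("  sigma0_sq :", signif(x$sigma0_sq, 4), "\n")
  cat("  sigma_sq  :", signif(x$sigma_sq, 4), "\n")
  invisible(x)
}

# first differences of a gridded trace (one per 10-day step)
trace_diffs <- function(trace) {
  if (length(trace$weights) < 2) stop("trace needs at least 2 grid points")
  diff(trace$weights)
}

#' Per-step, per-state emission log-densities
#'
#' Under the collapsed model (intercept redrawn each step and marginalised),
#' the weight increment \eqn{\Delta y_t = y_t - y_{t-1}} in state s is
#' Gaussian with mean `eta0[s]` and variance `sigma0_sq[s] + sigma_sq[s]`.
#' One row per step; a trace of T grid points yields T - 1 rows.
#'
#' @param params An [arhmm_params()] object.
#' @param trace A `gridded_trace` with at least 2 grid points.
#'
#' @return A (T-1) x K matrix of log densities.
#' @export
emission_stats <- function(params, trace) {
  d <- trace_diffs(trace)
  v <- params$sigma0_sq + params$sigma_sq
  if (any(v <= 0)) stop("total emission variance must be positive")
  matrix(vapply(seq_len(params$K),
                function(s) stats::dnorm(d, params$eta0[s], sqrt(v[s]),
                                         log = TRUE),
                numeric(length(d))),
         ncol = params$K)
}

# scaled forward-backward on a matrix of log emission densities.
# Returns gamma (Tm x K), xi ((Tm-1) x K x K), loglik.
fb_core <- function(log_e, pi0, A) {
  log_e <- matrix(log_e, ncol = length(pi0))
  Tm <- nrow(log_e)
  K <- ncol(log_e)
  m <- apply(log_e, 1, max)
  e <- exp(log_e - m)
  alpha <- matrix(0, Tm, K)
  cc <- numeric(Tm)
  a <- pi0 * e[1, ]
  cc[1] <- sum(a)
  alpha[1, ] <- a / cc[1]
  if (Tm > 1) {
    for (t in 2:Tm) {
      a <- as.numeric(alpha[t - 1, ] %*% A) * e[t, ]
      cc[t] <- sum(a)
      alpha[t, ] <- a / cc[t]
    }
  }
  beta <- matrix(1, Tm, K)
  if (Tm > 1) {
    for (t in (Tm - 1):1)
      beta[t, ] <- as.numeric(A %*% (e[t + 1, ] * beta[t + 1, ])) / cc[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- array(0, c(max(Tm - 1, 0), K, K))
  if (Tm > 1) {
    for (t in 1:(Tm - 1)) {
      x <- (alpha[t, ] %o% (e[t + 1, ] * beta[t + 1, ])) * A / cc[t + 1]
      xi[t, , ] <- x / sum(x)
    }
  }
  list(gamma = gamma, xi = xi, loglik = sum(log(cc)) + sum(m))
}

#' Exact smoothing posteriors for one trace
#'
#' Runs the (scaled) forward-backward recursions on the first differences
#' of a gridded trace under the collapsed emission model, returning the
#' per-step state marginals \eqn{\gamma}, pairwise marginals \eqn{\xi}, the
#' exact marginal log-likelihood, and the per-step MAP state path (argmax
#' of each \eqn{\gamma} row; ties go to the lowest state index).
#'
#' Posterior rows index the T - 1 weight increments; `step_times` holds the
#' grid day at the right endpoint of each step.
#'
#' @inheritParams emission_stats
#'
#' @return An object of class `posterior_states` with fields `gamma`, `xi`,
#'   `loglik`, `map_path`, `step_times`, `state_labels`.
#' @export
forward_backward <- function(params, trace) {
  log_e <- emission_stats(params, trace)
  fb <- fb_core(log_e, params$pi0, params$A)
  structure(
    list(gamma = fb$gamma, xi = fb$xi, loglik = fb$loglik,
         map_path = apply(fb$gamma, 1, which.max),
         step_times = trace$grid_times[-1],
         state_labels = attr(params, "state_labels")),
    class = "posterior_states"
  )
}

#' Decode a trace into its most probable state sequence
#'
#' Per-step argmax of the smoothing marginals (not Viterbi): each step is
#' assigned the state with the highest posterior probability.
#'
#' @inheritParams emission_stats
#'
#' @return A `posterior_states` object (see [forward_backward()]).
#' @export
decode <- function(params, trace) forward_backward(params, trace)

#' Semantic labels for a 3-state model
#'
#' States are named by the sign and magnitude of their intercept means:
#' the largest `eta0` is `growth`, the smallest `decline`, the remaining
#' state `steady`. Exact ties are resolved by assigning the state with the
#' smaller noise variance to `steady`. For K != 3 ordinal rank labels are
#' returned instead.
#'
#' @param params An [arhmm_params()] object.
#'
#' @return Character vector of length K: the label of each state index.
#' @export
label_states <- function(params) {
  K <- params$K
  if (K != 3) {
    r <- rank(-params$eta0, ties.method = "first")
    return(paste0("rank", r))
  }
  labs <- character(3)
  labs[state_order(params)] <- c("growth", "steady", "decline")
  labs
}

# permutation placing states in (growth, steady, decline) position order:
# decreasing intercept, with exact ties resolved by assigning the state
# with the smaller noise variance to the steady slot
state_order <- function(params) {
  ord <- order(-params$eta0, params$sigma_sq)
  if (params$K != 3) return(ord)
  eta <- params$eta0
  sig <- params$sigma_sq
  if (eta[ord[1]] == eta[ord[2]]) {
    # growth/steady tie: the quieter state is steady, noisier is growth
    pair <- ord[1:2]
    ord[1:2] <- pair[order(-sig[pair])]
  }
  if (eta[ord[2]] == eta[ord[3]]) {
    # steady/decline tie: the quieter state is steady
    pair <- ord[2:3]
    ord[2:3] <- pair[order(sig[pair])]
  }
  ord
}

# permute states of a params object by index vector `perm`
# (new state i = old state perm[i])
permute_params <- function(params, perm) {
  arhmm_params(params$pi0[perm], params$A[perm, perm, drop = FALSE],
               params$eta0[perm], params$sigma0_sq[perm],
               params$sigma_sq[perm])
}

# kmeans-based initialization for a restart
init_params <- function(d_all, K, sticky = 0.9) {
  if (K == 1) {
    centers <- mean(d_all)
  } else {
    km <- suppressWarnings(stats::kmeans(d_all, centers = K, nstart = 3,
                                         iter.max = 50))
    centers <- as.numeric(km$centers)
  }
  v <- max(stats::var(d_all) / K, 1e-4)
  A <- matrix((1 - sticky) / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) sticky else 1
  arhmm_params(rep(1 / K, K), A, centers, rep(v / 2, K), rep(v / 2, K))
}

# E-step over all traces under the collapsed emission model.
# Returns expected sufficient statistics and total loglik.
collapsed_estep <- function(params, diffs) {
  K <- params$K
  init <- numeric(K)
  trans <- matrix(0, K, K)
  sum_g <- numeric(K)
  sum_gd <- numeric(K)
  sum_gd2 <- numeric(K)
  ll <- 0
  for (d in diffs) {
    v <- params$sigma0_sq + params$sigma_sq
    log_e <- vapply(seq_len(K), function(s)
      stats::dnorm(d, params$eta0[s], sqrt(v[s]), log = TRUE),
      numeric(length(d)))
    fb <- fb_core(log_e, params$pi0, params$A)
    init <- init + fb$gamma[1, ]
    if (dim(fb$xi)[1] > 0)
      trans <- trans + apply(fb$xi, c(2, 3), sum)
    sum_g <- sum_g + colSums(fb$gamma)
    sum_gd <- sum_gd + colSums(fb$gamma * d)
    sum_gd2 <- sum_gd2 + colSums(fb$gamma * d^2)
    ll <- ll + fb$loglik
  }
  list(init = init, trans = trans, sum_g = sum_g, sum_gd = sum_gd,
       sum_gd2 = sum_gd2, loglik = ll)
}

normalize_rows <- function(A) {
  K <- ncol(A)
  rs <- rowSums(A)
  A <- A / ifelse(rs > 0, rs, 1)
  A[rs <= 0, ] <- 1 / K
  A
}

collapsed_mstep <- function(ss, var_floor = 1e-6) {
  K <- length(ss$init)
  pi0 <- ss$init / sum(ss$init)
  A <- normalize_rows(ss$trans)
  eta0 <- ss$sum_gd / ss$sum_g
  v <- pmax(ss$sum_gd2 / ss$sum_g - eta0^2, var_floor)
  arhmm_params(pi0, A, eta0, rep(0, K), v)
}

# one variational-EM pass for the random-intercept model; q(phi_{m,s}) is
# Gaussian per trace and state.
ri_estep <- function(params, diffs, q_mu, q_v) {
  K <- params$K
  M <- length(diffs)
  init <- numeric(K)
  trans <- matrix(0, K, K)
  sum_g <- numeric(K)
  resid <- numeric(K)      # sum_t gamma * ((d - mu)^2 + v)
  elbo <- 0
  gam_list <- vector("list", M)
  for (m in seq_len(M)) {
    d <- diffs[[m]]
    mu <- q_mu[m, ]
    vv <- q_v[m, ]
    log_e <- t(-0.5 * log(2 * pi * params$sigma_sq) -
                 (outer(-mu, d, "+")^2 + vv) / (2 * params$sigma_sq))
    fb <- fb_core(log_e, params$pi0, params$A)
    gam_list[[m]] <- fb$gamma
    init <- init + fb$gamma[1, ]
    if (dim(fb$xi)[1] > 0)
      trans <- trans + apply(fb$xi, c(2, 3), sum)
    sum_g <- sum_g + colSums(fb$gamma)
    resid <- resid + colSums(fb$gamma * (outer(d, mu, "-")^2 +
                                           matrix(vv, length(d), K,
                                                  byrow = TRUE)))
    kl <- 0.5 * (log(params$sigma0_sq / vv) +
                   (vv + (mu - params$eta0)^2) / params$sigma0_sq - 1)
    elbo <- elbo + fb$loglik - sum(kl)
  }
  list(init = init, trans = trans, sum_g = sum_g, resid = resid,
       elbo = elbo, gam_list = gam_list)
}

#' Fit the autoregressive hidden Markov model
#'
#' Two inference variants are provided. `"collapsed"` treats the state
#' intercept as redrawn independently at every step; marginalising it gives
#' an exact HMM on first differences with emission
#' \eqn{N(\eta_{0s}, \sigma^2_{0s} + \sigma^2_s)}, fitted by exact EM
#' (closed-form M-steps). `"random_intercept"` keeps one intercept per
#' animal and state, drawn once per trace from
#' \eqn{N(\eta_{0s}, \sigma^2_{0s})}, and fits a structured mean-field
#' variational EM with a Gaussian posterior over each intercept; restarts
#' are compared on the final ELBO. In both variants the best of `n_init`
#' seeded restarts is returned and states are relabeled in decreasing
#' intercept order (for K = 3: growth, steady, decline).
#'
#' @param traces List of `gridded_trace` objects (each with >= 3 grid
#'   points).
#' @param K Number of latent states.
#' @param n_init Number of random restarts.
#' @param seed Integer seed; restart r uses `seed + r - 1`.
#' @param mode `"random_intercept"` (default) or `"collapsed"`.
#' @param max_iter Maximum EM/VB iterations per restart.
#' @param tol Relative objective-change convergence tolerance.
#'
#' @return An object of class `arhmm_fit` with fields `params`,
#'   `state_labels`, `elbo_trace`, `loglik`, `seed`, `n_iter`, `converged`,
#'   `mode`, and expected sufficient statistics `suff` (used by
#'   [select_model_order()]).
#' @export
fit_arhmm <- function(traces, K, n_init = 10, seed = 1,
                      mode = c("random_intercept", "collapsed"),
                      max_iter = 500, tol = 1e-8) {
  mode <- match.arg(mode)
  stopifnot(K >= 1, n_init >= 1)
  traces <- Filter(function(tr) length(tr$weights) >= 3, traces)
  if (length(traces) == 0) stop("no traces with at least 3 grid points")
  diffs <- lapply(traces, trace_diffs)
  best <- NULL
  for (r in seq_len(n_init)) {
    set.seed(seed + r - 1)
    fit <- if (mode == "collapsed")
      fit_collapsed_once(diffs, K, max_iter, tol)
    else
      fit_ri_once(diffs, K, max_iter, tol)
    if (is.null(best) || fit$objective > best$objective) {
      best <- fit
      best$seed <- seed + r - 1
    }
  }
  # relabel states in decreasing intercept order
  perm <- state_order(best$params)
  params <- permute_params(best$params, perm)
  suff <- list(init = best$suff$init[perm],
               trans = best$suff$trans[perm, perm, drop = FALSE],
               sum_g = best$suff$sum_g[perm])
  labels <- label_states(params)
  attr(params, "state_labels") <- labels
  structure(
    list(params = params, state_labels = labels,
         elbo_trace = best$elbo_trace, loglik = best$objective,
         seed = best$seed, n_iter = length(best$elbo_trace),
         converged = best$converged, mode = mode, suff = suff,
         n_traces = length(traces)),
    class = "arhmm_fit"
  )
}

fit_collapsed_once <- function(diffs, K, max_iter, tol) {
  d_all <- unlist(diffs)
  params <- init_params(d_all, K)
  trace_obj <- numeric(0)
  converged <- FALSE
  ss <- NULL
  for (it in seq_len(max_iter)) {
    ss <- collapsed_estep(params, diffs)
    trace_obj <- c(trace_obj, ss$loglik)
    if (it > 1) {
      rel <- abs(ss$loglik - trace_obj[it - 1]) /
        (abs(trace_obj[it - 1]) + 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
    params <- collapsed_mstep(ss)
  }
  if (!converged)
    warning("collapsed EM did not converge within max_iter")
  list(params = params, objective = trace_obj[length(trace_obj)],
       elbo_trace = trace_obj, converged = converged,
       suff = list(init = ss$init, trans = ss$trans, sum_g = ss$sum_g))
}

fit_ri_once <- function(diffs, K, max_iter, tol, var_floor = 1e-6) {
  d_all <- unlist(diffs)
  params <- init_params(d_all, K)
  # give the intercept prior a non-degenerate share of the variance
  params$sigma0_sq <- pmax(params$sigma0_sq, 1e-4)
  M <- length(diffs)
  q_mu <- matrix(params$eta0, M, K, byrow = TRUE)
  q_v <- matrix(params$sigma0_sq, M, K, byrow = TRUE)
  gam_list <- NULL
  trace_obj <- numeric(0)
  converged <- FALSE
  es <- NULL
  for (it in seq_len(max_iter)) {
    # update q(phi) given current gamma (first pass: prior-centered)
    if (!is.null(gam_list)) {
      for (m in seq_len(M)) {
        g <- gam_list[[m]]
        d <- diffs[[m]]
        prec <- 1 / params$sigma0_sq + colSums(g) / params$sigma_sq
        q_v[m, ] <- 1 / prec
        q_mu[m, ] <- q_v[m, ] * (params$eta0 / params$sigma0_sq +
                                   colSums(g * d) / params$sigma_sq)
      }
    }
    es <- ri_estep(params, diffs, q_mu, q_v)
    gam_list <- es$gam_list
    trace_obj <- c(trace_obj, es$elbo)
    if (it > 1) {
      rel <- abs(es$elbo - trace_obj[it - 1]) /
        (abs(trace_obj[it - 1]) + 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
    # M-step
    pi0 <- es$init / sum(es$init)
    A <- normalize_rows(es$trans)
    eta0 <- colMeans(q_mu)
    sigma0_sq <- pmax(colMeans((q_mu - matrix(eta0, M, K, byrow = TRUE))^2 +
                                 q_v), var_floor)
    sigma_sq <- pmax(es$resid / es$sum_g, var_floor)
    params <- arhmm_params(pi0, A, eta0, sigma0_sq, sigma_sq)
  }
  if (!converged)
    warning("variational EM did not converge within max_iter")
  list(params = params, objective = trace_obj[length(trace_obj)],
       elbo_trace = trace_obj, converged = converged,
       suff = list(init = es$init, trans = es$trans, sum_g = es$sum_g))
}

#' @export
print.arhmm_fit <- function(x, ...) {
  cat(sprintf("<arhmm_fit: K = %d, mode = %s, %s after %d iterations>\n",
              x$params$K, x$mode,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("  final objective:", format(x$loglik, digits = 8), "\n")
  cat("  state labels   :", x$state_labels, "\n")
  print(x$params)
  invisible(x)
}

# total collapsed log-likelihood of a set of traces under params
arhmm_loglik <- function(params, traces) {
  sum(vapply(traces, function(tr) forward_backward(params, tr)$loglik,
             numeric(1)))
}

# draw one parameter vector from the approximate posterior implied by the
# expected sufficient statistics of a fit: Dirichlet over pi0 and the A
# rows (expected counts), Normal over the intercept means (asymptotic
# variance v_tot / N_s); variances are held at their point estimates,
# where the deviance is locally flat and draws would only add noise
draw_params <- function(fit) {
  p <- fit$params
  K <- p$K
  rdir <- function(a) { g <- stats::rgamma(length(a), a); g / sum(g) }
  pi0 <- rdir(fit$suff$init + 1)
  A <- t(vapply(seq_len(K), function(i) rdir(fit$suff$trans[i, ] + 1),
                numeric(K)))
  n_s <- pmax(fit$suff$sum_g, 1)
  v_tot <- p$sigma0_sq + p$sigma_sq
  eta0 <- stats::rnorm(K, p$eta0, sqrt(v_tot / n_s))
  arhmm_params(pi0, A, eta0, p$sigma0_sq, p$sigma_sq)
}

# mean of the same approximate posterior draw_params() samples from:
# Dirichlet means for pi0 and the A rows, point estimates elsewhere.
# Evaluating the plug-in deviance here (rather than at the raw EM
# maximizer, whose near-zero transition entries can explode on held-out
# sequences) keeps the effective-parameter term non-negative.
posterior_mean_params <- function(fit) {
  p <- fit$params
  init <- fit$suff$init + 1
  trans <- fit$suff$trans + 1
  arhmm_params(init / sum(init), normalize_rows(trans), p$eta0,
               p$sigma0_sq, p$sigma_sq)
}

#' Select the number of latent states by held-out DIC
#'
#' For each candidate K the model is fitted on the training traces and the
#' deviance information criterion is evaluated on the held-out traces:
#' \deqn{DIC = 2 \bar{D} - D(\hat{\theta}),}
#' where \eqn{D(\theta) = -2 \log p(\mathrm{heldout} \mid \theta)},
#' \eqn{\hat\theta} is the fitted point estimate and \eqn{\bar D} averages
#' the deviance over draws from an approximate parameter posterior
#' (Dirichlet over the initial/transition rows from expected counts,
#' Gaussian over the state intercepts). The K minimising DIC is returned.
#'
#' @param train,heldout Disjoint lists of `gridded_trace` objects.
#' @param K_range Integer vector of candidate state counts.
#' @param n_init Restarts per fit.
#' @param seed Integer seed.
#' @param mode Inference variant passed to [fit_arhmm()].
#' @param n_draws Posterior draws used for the mean deviance.
#' @param ... Further arguments (e.g. `max_iter`) passed to [fit_arhmm()].
#'
#' @return List with `best_K`, `dic` (named per K), and `fits`.
#' @export
select_model_order <- function(train, heldout, K_range, n_init = 3,
                               seed = 1, mode = "collapsed", n_draws = 50,
                               ...) {
  if (length(K_range) == 0) stop("K_range must be non-empty")
  ids_tr <- vapply(train, `[[`, character(1), "animal_id")
  ids_ho <- vapply(heldout, `[[`, character(1), "animal_id")
  if (length(intersect(ids_tr, ids_ho)) > 0)
    stop("train and heldout sets must be disjoint by animal_id")
  dic <- stats::setNames(numeric(length(K_range)), K_range)
  fits <- list()
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    fit <- fit_arhmm(train, K, n_init = n_init, seed = seed, mode = mode,
                     ...)
    d_hat <- -2 * arhmm_loglik(posterior_mean_params(fit), heldout)
    set.seed(seed + 10000 + K)
    d_bar <- mean(vapply(seq_len(n_draws), function(s)
      -2 * arhmm_loglik(draw_params(fit), heldout), numeric(1)))
    dic[i] <- 2 * d_bar - d_hat
    fits[[as.character(K)]] <- fit
  }
  list(best_K = K_range[which.min(dic)], dic = dic, fits = fits)
}

#' Stratified train/held-out split of a cohort
#'
#' Splits traces by animal into a training and a held-out set, stratified
#' by diet group (the study trains on 70% of traces from each diet).
#'
#' @param traces List of trace objects carrying a `diet` field.
#' @param frac Training fraction (default 0.7).
#' @param seed Integer seed.
#'
#' @return List with elements `train` and `heldout`.
#' @export
split_train_heldout <- function(traces, frac = 0.7, seed = 1) {
  diets <- vapply(traces, `[[`, character(1), "diet")
  set.seed(seed)
  train_idx <- unlist(lapply(split(seq_along(traces), diets), function(ix) {
    n_tr <- max(1, round(frac * length(ix)))
    sample(ix, n_tr)
  }), use.names = FALSE)
  list(train = traces[sort(train_idx)],
       heldout = traces[-sort(train_idx)])
}

#' Tidy posterior table for a set of decoded traces
#'
#' @param fit An [fit_arhmm()] result.
#' @param traces List of `gridded_trace` objects.
#'
#' @return Data frame with columns `animal_id`, `grid_day`, one posterior
#'   column per state label (e.g. `p_growth`), and `map_state`.
#' @export
posterior_table <- function(fit, traces) {
  labs <- fit$state_labels
  out <- do.call(rbind, lapply(traces, function(tr) {
    ps <- forward_backward(fit$params, tr)
    df <- data.frame(animal_id = tr$animal_id, grid_day = ps$step_times)
    for (s in seq_along(labs)) df[[paste0("p_", labs[s])]] <- ps$gamma[, s]
    df$map_state <- labs[ps$map_path]
    df
  }))
  rownames(out) <- NULL
  out
}
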