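test_that("emission log-densities match the Gaussian increment model", {
  p <- arhmm_params(c(1, 0, 0) / 1, diag(3), c(0.6, 0, -0.9),
                    rep(0.01, 3), rep(0.03, 3))
  # increment exactly at a state's mean attains the Gaussian mode
  tr <- make_trace(c(30, 30.6))
  le <- emission_stats(p, tr)
  expect_equal(le[1, 1], -0.5 * log(2 * pi * 0.04))
  # zero intercept variance reduces to the plain AR noise density
  p0 <- arhmm_params(c(1, 0, 0), diag(3), c(0.6, 0, -0.9), rep(0, 3),
                     rep(0.03, 3))
  le0 <- emission_stats(p0, make_trace(c(30, 30.2)))
  expect_equal(le0[1, 2], dnorm(0.2, 0, sqrt(0.03), log = TRUE))
  # a zero increment is most likely under the zero-drift state
  le3 <- emission_stats(p, make_trace(c(30, 30)))
  expect_equal(which.max(le3[1, ]), 2)
})

test_that("forward-backward matches exhaustive path enumeration", {
  for (seed in 1:5) {
    p <- random_params(K = 3, seed = seed)
    set.seed(seed + 100)
    tr <- make_trace(cumsum(c(30, rnorm(5, 0, 0.5))))
    ps <- forward_backward(p, tr)
    bf <- brute_force_posteriors(p, tr)
    expect_lt(max(abs(ps$gamma - bf$gamma)), 1e-8)
    expect_lt(max(abs(ps$xi - bf$xi)), 1e-8)
    expect_lt(abs(ps$loglik - bf$loglik), 1e-8)
  }
})

test_that("posterior marginals are internally consistent", {
  for (seed in 1:10) {
    p <- random_params(K = sample(2:4, 1), seed = seed)
    set.seed(seed)
    tr <- make_trace(cumsum(c(25, rnorm(30, 0.1, 0.6))))
    ps <- forward_backward(p, tr)
    Tm <- nrow(ps$gamma)
    expect_equal(rowSums(ps$gamma), rep(1, Tm), tolerance = 1e-8)
    expect_equal(apply(ps$xi, c(1, 2), sum), ps$gamma[-Tm, ],
                 tolerance = 1e-8)
    expect_equal(apply(ps$xi, c(1, 3), sum), ps$gamma[-1, ],
                 tolerance = 1e-8)
  }
})

test_that("single-state and symmetric models decode trivially", {
  p1 <- arhmm_params(1, matrix(1), 0.1, 0.01, 0.02)
  tr <- make_trace(c(30, 30.2, 30.1, 30.4))
  ps <- forward_backward(p1, tr)
  expect_equal(as.numeric(ps$gamma), rep(1, 3))
  expect_equal(ps$loglik, sum(emission_stats(p1, tr)))
  # identical emissions + uniform chain => uniform posteriors
  pu <- arhmm_params(rep(1 / 3, 3), matrix(1 / 3, 3, 3), rep(0, 3),
                     rep(0, 3), rep(0.04, 3))
  psu <- forward_backward(pu, tr)
  expect_equal(as.numeric(psu$gamma), rep(1 / 3, 9), tolerance = 1e-12)
})

test_that("decoding uses per-time argmax with ties to the lowest index", {
  expect_equal(which.max(c(0.1, 0.7, 0.2)), 2)
  pu <- arhmm_params(rep(1 / 3, 3), matrix(1 / 3, 3, 3), rep(0, 3),
                     rep(0, 3), rep(0.04, 3))
  ps <- decode(pu, make_trace(c(30, 30.1, 30.2)))
  expect_equal(ps$map_path, c(1, 1))  # exact three-way tie -> state 1
})

test_that("state labels follow intercept order with variance tie-break", {
  lab <- function(eta, sig = c(0.02, 0.02, 0.02))
    label_states(arhmm_params(rep(1 / 3, 3), matrix(1 / 3, 3, 3), eta,
                              rep(0, 3), sig))
  expect_equal(lab(c(0.5, 0, -0.6)), c("growth", "steady", "decline"))
  expect_equal(lab(c(-0.6, 0.5, 0)), c("decline", "growth", "steady"))
  # tied top intercepts: the noisier state is growth, the quieter steady
  expect_equal(lab(c(0.5, 0.5, -0.6), c(0.08, 0.01, 0.02)),
               c("growth", "steady", "decline"))
  expect_equal(lab(c(0.5, 0.5, -0.6), c(0.01, 0.08, 0.02)),
               c("steady", "growth", "decline"))
  k2 <- arhmm_params(c(0.5, 0.5), matrix(0.5, 2, 2), c(0.3, -0.1),
                     rep(0, 2), rep(0.02, 2))
  expect_equal(label_states(k2), c("rank1", "rank2"))
})

test_that("collapsed EM with one state reduces to sample moments", {
  set.seed(3)
  traces <- lapply(1:5, function(i)
    make_trace(cumsum(c(25, rnorm(40, 0.2, 0.5)))))
  fit <- fit_arhmm(traces, K = 1, n_init = 1, seed = 1,
                   mode = "collapsed")
  d <- unlist(lapply(traces, function(tr) diff(tr$weights)))
  expect_equal(fit$params$eta0, mean(d), tolerance = 1e-6)
  expect_equal(fit$params$sigma_sq, mean((d - mean(d))^2),
               tolerance = 1e-6)
})

test_that("EM and variational objectives are monotone non-decreasing", {
  truth <- default_truth()
  sim <- simulate_arhmm_traces(truth, 20, 40, seed = 21)
  for (mode in c("collapsed", "random_intercept")) {
    fit <- suppressWarnings(fit_arhmm(sim$traces, K = 3, n_init = 1,
                                      seed = 4, mode = mode))
    steps <- diff(fit$elbo_trace)
    expect_true(all(steps > -1e-6 * pmax(abs(fit$elbo_trace[-1]), 1)),
                info = mode)
  }
})

test_that("collapsed and random-intercept fits agree when the intercept
          variance vanishes", {
  truth <- default_truth()  # sigma0_sq = 0: collapsed-consistent data
  sim <- simulate_arhmm_traces(truth, 60, 80, seed = 31)
  fc <- fit_arhmm(sim$traces, K = 3, n_init = 2, seed = 5,
                  mode = "collapsed")
  fr <- suppressWarnings(fit_arhmm(sim$traces, K = 3, n_init = 2,
                                   seed = 5, mode = "random_intercept"))
  expect_equal(fc$params$eta0, fr$params$eta0, tolerance = 1e-3)
})

test_that("fitting recovers known parameters and the true state path", {
  truth <- default_truth()
  sim <- simulate_arhmm_traces(truth, 80, 80, seed = 41)
  fit <- fit_arhmm(sim$traces, K = 3, n_init = 2, seed = 6,
                   mode = "collapsed")
  # states come back in decreasing-intercept order matching the truth
  n_s <- fit$suff$sum_g
  se <- sqrt((fit$params$sigma0_sq + fit$params$sigma_sq) / n_s)
  expect_true(all(abs(fit$params$eta0 - truth$eta0) < 3 * se))
  acc <- mean(unlist(lapply(seq_along(sim$traces), function(i)
    decode(fit$params, sim$traces[[i]])$map_path == sim$paths[[i]])))
  expect_gt(acc, 0.9)
})

test_that("relabeling permutes parameters without changing the model", {
  p <- random_params(K = 3, seed = 9)
  perm <- c(3, 1, 2)
  pp <- bwdyn:::permute_params(p, perm)
  set.seed(2)
  tr <- make_trace(cumsum(c(30, rnorm(10, 0, 0.5))))
  ps1 <- forward_backward(p, tr)
  ps2 <- forward_backward(pp, tr)
  expect_equal(ps1$loglik, ps2$loglik, tolerance = 1e-12)
  expect_equal(ps1$gamma[, perm], ps2$gamma, tolerance = 1e-12)
})

test_that("train/held-out splits are stratified and disjoint", {
  truth <- default_truth()
  sim <- simulate_arhmm_traces(truth, 40, 10, seed = 8)
  diets <- rep(c("AL", "40"), each = 20)
  for (i in seq_along(sim$traces)) sim$traces[[i]]$diet <- diets[i]
  sp <- split_train_heldout(sim$traces, frac = 0.7, seed = 3)
  ids <- function(x) vapply(x, `[[`, character(1), "animal_id")
  expect_length(intersect(ids(sp$train), ids(sp$heldout)), 0)
  expect_equal(length(sp$train) + length(sp$heldout), 40)
  tr_diets <- vapply(sp$train, `[[`, character(1), "diet")
  expect_equal(as.numeric(table(tr_diets)), c(14, 14))
})

test_that("degenerate single-state data selects K = 1", {
  p1 <- arhmm_params(1, matrix(1), 0.1, 0, 0.04)
  sim <- simulate_arhmm_traces(p1, 30, 40, seed = 12)
  sp <- split_train_heldout(sim$traces, 0.7, seed = 2)
  sel <- suppressWarnings(
    select_model_order(sp$train, sp$heldout, K_range = c(1, 2),
                       n_init = 2, seed = 2, max_iter = 100))
  expect_equal(sel$best_K, 1)
})

test_that("posterior tables are tidy and complete", {
  truth <- default_truth()
  sim <- simulate_arhmm_traces(truth, 3, 20, seed = 14)
  fit <- suppressWarnings(fit_arhmm(sim$traces, K = 3, n_init = 1,
                                    seed = 1, mode = "collapsed",
                                    max_iter = 50))
  pt <- posterior_table(fit, sim$traces)
  expect_equal(nrow(pt), 3 * 19)
  expect_true(all(c("p_growth", "p_steady", "p_decline",
                    "map_state") %in% names(pt)))
  expect_equal(pt$p_growth + pt$p_steady + pt$p_decline,
               rep(1, nrow(pt)), tolerance = 1e-8)
})
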