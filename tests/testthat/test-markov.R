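test_that("forward-backward log-likelihood matches brute-force path enumeration", {
  set.seed(101)
  for (i in 1:100) {
    K <- sample(2:3, 1); Tn <- sample(2:4, 1)
    pi0 <- rexp(K); pi0 <- pi0 / sum(pi0)
    A <- matrix(rexp(K * K), K); A <- A / rowSums(A)
    LB <- matrix(log(runif(Tn * K)), Tn, K)
    last <- sample(seq_len(Tn), 1)
    if (last < Tn) LB[(last + 1):Tn, ] <- 0  # unobserved tail waves
    fb <- forward_backward(pi0, A, LB, last_obs = last)
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
    lp <- apply(paths, 1, function(z) {
      v <- log(pi0[z[1]]) + LB[1, z[1]]
      for (t in 2:Tn) v <- v + log(A[z[t - 1], z[t]]) + LB[t, z[t]]
      v
    })
    m <- max(lp)
    expect_equal(fb$loglik, m + log(sum(exp(lp - m))), tolerance = 1e-10)
    ## smoothed marginals are proper distributions
    expect_equal(rowSums(fb$gamma), rep(1, Tn), tolerance = 1e-9)
  }
})

test_that("single-class and degenerate-emission cases are exact", {
  ## K = 1: loglik is the sum of the class-1 log-densities
  LB <- matrix(log(runif(4)), 4, 1)
  fb <- forward_backward(1, matrix(1, 1, 1), LB)
  expect_equal(fb$loglik, sum(LB))
  expect_true(all(fb$gamma == 1))
  ## near-degenerate emissions concentrate the smoothed path on the truth
  K <- 3
  z <- c(2, 3, 3, 1)
  LB <- matrix(log(1e-12), 4, K)
  LB[cbind(1:4, z)] <- 0
  A <- matrix(1 / K, K, K)
  fb <- forward_backward(rep(1 / K, K), A, LB)
  expect_true(all(fb$gamma[cbind(1:4, z)] > 1 - 1e-6))
})

test_that("deleting unit-emission waves leaves the likelihood unchanged", {
  set.seed(17)
  K <- 3
  pi0 <- rep(1 / 3, 3)
  A <- matrix(rexp(9), 3); A <- A / rowSums(A)
  LB <- rbind(matrix(log(runif(2 * K)), 2, K), 0, 0)
  full <- forward_backward(pi0, A, LB, last_obs = 2)
  shortd <- forward_backward(pi0, A, LB[1:2, , drop = FALSE])
  expect_equal(full$loglik, shortd$loglik, tolerance = 1e-12)
})

test_that("degenerate emissions give the empirical-chain closed form", {
  E <- degenerate_emissions(3)
  cfg <- generator_config(n_individuals = 600, n_waves = 4,
                          pi0 = c(0.5, 0.3, 0.2),
                          A = rbind(c(0.8, 0.1, 0.1), c(0.2, 0.7, 0.1),
                                    c(0.1, 0.2, 0.7)),
                          emissions = E, baseline_delta = rep(0, 6),
                          retention = rep(0.9, 3), dropout = "bernoulli",
                          seed = 19)
  d <- simulate_panel(cfg)
  meas <- measurement_model(stats::qlogis(E), rep(0, 6))
  mk <- fit_latent_markov(d, meas, se = FALSE, tol = 1e-12,
                          max_iter = 10000)
  emp <- truth_transitions(d, 3)
  expect_equal(unname(mk$A), unname(as.matrix(emp)), tolerance = 1e-8)
  first <- !duplicated(d$person_id[order(d$person_id, d$wave)])
  z0 <- d$latent_class_truth[order(d$person_id, d$wave)][first]
  expect_equal(unname(mk$pi0),
               as.numeric(table(factor(z0, 1:3)) / length(z0)),
               tolerance = 1e-8)
})

test_that("Markov EM keeps rows stochastic and is start-stable", {
  cfg <- two_class_config(n = 500, seed = 21)
  cfg$n_waves <- 3L; cfg$retention <- c(0.9, 0.9)
  d <- simulate_panel(cfg)
  fit <- fit_lca(d, 2, n_starts = 8, start_iters = 50, seed = 3)
  lls <- vapply(1:20, function(r) {
    set.seed(1000 + r)
    p <- rexp(2); p <- p / sum(p)
    Ai <- matrix(rexp(4), 2); Ai <- Ai / rowSums(Ai)
    m <- fit_latent_markov(d, fit, se = FALSE, init_pi0 = p, init_A = Ai)
    expect_equal(unname(rowSums(m$A)), c(1, 1), tolerance = 1e-12)
    m$loglik
  }, numeric(1))
  expect_lt(max(lls) - min(lls), 1e-6 * abs(mean(lls)))
})

test_that("transition table is a labeled percentage matrix", {
  A <- diag(4)
  fit <- structure(list(pi0 = rep(0.25, 4), A = A), class = "markov_fit")
  tt <- transition_table(fit)
  expect_equal(diag(tt), rep(100, 4), ignore_attr = TRUE)
  expect_true(all(tt[upper.tri(tt) | lower.tri(tt)] == 0))
  ## generic fit: rows sum to 100 within rounding
  cfg <- two_class_config(n = 300, seed = 33)
  d <- simulate_panel(cfg)
  f <- fit_lca(d, 2, n_starts = 4, start_iters = 30, seed = 2)
  mk <- fit_latent_markov(d, f, se = FALSE)
  expect_true(all(abs(rowSums(transition_table(mk)) - 100) <= 0.05))
})

test_that("parameter recovery error shrinks with cohort size", {
  errs <- vapply(c(2000L, 20000L), function(n) {
    cfg <- generator_config(n_individuals = n, dropout = "bernoulli",
                            seed = 77)
    d <- simulate_panel(cfg)
    meas <- measurement_model(stats::qlogis(default_emissions()),
                              rep(0.5, 8))
    mk <- fit_latent_markov(d, meas, se = FALSE)
    max(abs(mk$A[1:2, ] - default_transitions()[1:2, ]))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.02)
})

test_that("cluster-robust standard errors are positive and sane", {
  cfg <- two_class_config(n = 800, seed = 55)
  cfg$n_waves <- 3L; cfg$retention <- c(0.9, 0.9)
  d <- simulate_panel(cfg)
  f <- fit_lca(d, 2, n_starts = 8, start_iters = 50, seed = 2)
  mk <- fit_latent_markov(d, f)
  expect_true(all(mk$se_pi0 > 0))
  expect_true(all(mk$se_A > 0))
  ## SE of the initial proportion roughly binomial at this separation
  expect_lt(abs(mk$se_pi0[1] - sqrt(0.7 * 0.3 / 800)), 0.01)
})
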