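test_that("emission log-probability equals the Bernoulli product oracle", {
  set.seed(7)
  K <- 3L; J <- 8L
  meas <- measurement_model(matrix(rnorm(K * J), K, J), runif(J, 0, 1))
  for (i in 1:20) {
    y <- rbinom(J, 1, 0.5)
    cc <- sample.int(K, 1)
    isb <- runif(1) < 0.5
    p <- emission_probs(meas, isb)[cc, ]
    oracle <- log(prod(ifelse(y == 1, p, 1 - p)))
    expect_equal(emission_logprob(meas, y, cc, isb), oracle, tolerance = 1e-12)
  }
  ## symmetric case: all logits zero
  m0 <- measurement_model(matrix(0, 2, 8))
  expect_equal(emission_logprob(m0, rbinom(8, 1, 0.5), 1), -8 * log(2))
  ## delta = 0: baseline flag irrelevant
  expect_equal(emission_logprob(meas, rep(1, J), 2, FALSE),
               emission_logprob(measurement_model(meas$beta0, rep(0, J)),
                                rep(1, J), 2, TRUE))
  expect_error(emission_logprob(meas, c(0, 1, 2, 0, 1, 0, 1, 0), 1), "binary")
})

test_that("one-class fit recovers marginal prevalences in closed form", {
  d <- simulate_pooled(two_class_config(seed = 2), 600)
  fit <- fit_lca(d, 1, n_starts = 2, start_iters = 20, seed = 1)
  Y <- lcpanel:::panel_matrix(d)
  phat <- colMeans(Y)
  expect_equal(as.numeric(emission_probs(fit$measurement)), unname(phat),
               tolerance = 1e-7)
  expect_equal(fit$weights, 1)
  ll <- sum(Y %*% log(phat) + (1 - Y) %*% log(1 - phat))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("well-separated two-class parameters are recovered", {
  cfg <- two_class_config(seed = 8)
  d <- simulate_pooled(cfg, 5000)
  fit <- fit_lca(d, 2, n_starts = 16, start_iters = 100, seed = 4)
  perm <- match_classes(emission_probs(fit$measurement), cfg$emissions)
  w <- fit$weights[perm]
  expect_lt(abs(w[1] - 0.7), 3 * sqrt(0.7 * 0.3 / 5000) + 0.01)
  E <- emission_probs(fit$measurement)[perm, ]
  se <- sqrt(cfg$emissions * (1 - cfg$emissions) /
               (5000 * matrix(c(0.7, 0.3), 2, 6)))
  expect_true(all(abs(E - cfg$emissions) < 4 * se + 0.01))
})

test_that("EM log-likelihood is monotone and label order deterministic", {
  d <- simulate_pooled(two_class_config(seed = 5), 1000)
  fit <- fit_lca(d, 3, n_starts = 8, start_iters = 50, seed = 9)
  expect_true(all(diff(fit$trace) >= -1e-8 * abs(fit$trace[-1])))
  expect_true(all(diff(fit$weights) <= 1e-12))
  ## permutation invariance at an identified class count: shuffling the
  ## records changes neither the maximized likelihood nor the parameters
  set.seed(3)
  ds <- d[sample(nrow(d)), ]
  ds$person_id <- seq_len(nrow(ds))  # keep keys unique
  ds <- as_panel(as.data.frame(ds), indicators = attr(d, "indicators"))
  f1 <- fit_lca(d, 2, n_starts = 8, start_iters = 50, seed = 9)
  f2 <- fit_lca(ds, 2, n_starts = 8, start_iters = 50, seed = 9)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
  expect_equal(f2$weights, f1$weights, tolerance = 1e-5)
  expect_equal(f2$measurement$beta0, f1$measurement$beta0, tolerance = 1e-4)
})

test_that("pattern-weighted likelihood equals record-wise computation", {
  d <- simulate_pooled(two_class_config(seed = 12), 800)
  fit <- fit_lca(d, 2, n_starts = 8, start_iters = 50, seed = 2)
  LD <- class_log_densities(fit, d)
  ll_rec <- sum(apply(sweep(LD, 2, log(fit$weights), `+`), 1,
                      function(a) { m <- max(a); m + log(sum(exp(a - m))) }))
  expect_equal(fit$loglik, ll_rec, tolerance = 1e-8)
})

test_that("posterior probabilities match brute-force Bayes rule", {
  cfg <- two_class_config(seed = 3, delta = c(0.2, 0.5, 0.3, 0.6, 0.4, 0.1))
  d <- simulate_panel(cfg)
  fit <- fit_lca(d, 2, n_starts = 8, start_iters = 50, seed = 6)
  post <- posterior_classes(fit, d)
  expect_equal(unname(rowSums(post)), rep(1, nrow(d)))
  i <- c(1L, 57L, nrow(d))
  for (ii in i) {
    y <- lcpanel:::panel_matrix(d)[ii, ]
    joint <- vapply(1:2, function(cc) {
      fit$weights[cc] *
        exp(emission_logprob(fit$measurement, y, cc, d$wave[ii] == 0))
    }, numeric(1))
    expect_equal(post[ii, ], setNames(joint / sum(joint), colnames(post)),
                 tolerance = 1e-10)
  }
  ## K = 1: posterior identically 1
  f1 <- fit_lca(d, 1, n_starts = 1, start_iters = 5, seed = 1)
  expect_true(all(posterior_classes(f1, d) == 1))
})

test_that("class-specific log-densities are exact and round-trip through CSV", {
  cfg <- two_class_config(seed = 4, delta = rep(0.4, 6))
  d <- simulate_panel(cfg)
  fit <- fit_lca(d, 2, n_starts = 8, start_iters = 50, seed = 2)
  LD <- class_log_densities(fit, d)
  ## identity: exp(LD) weighted and normalized reproduces the posterior
  w <- exp(sweep(LD, 2, log(fit$weights), `+`))
  expect_equal(w / rowSums(w), posterior_classes(fit, d),
               tolerance = 1e-12, ignore_attr = TRUE)
  ## CSV round trip at full precision
  tmp <- tempfile(fileext = ".csv")
  df <- cbind(as.data.frame(d), as.data.frame(LD))
  utils::write.csv(df, tmp, row.names = FALSE)
  back <- utils::read.csv(tmp)
  expect_equal(as.matrix(back[, colnames(LD)]), LD, tolerance = 1e-12,
               ignore_attr = TRUE)
  ## one-class, uniform emissions: every density is -J log 2
  m0 <- measurement_model(matrix(0, 1, 6))
  expect_true(all(abs(class_log_densities(m0, d) + 6 * log(2)) < 1e-12))
})

test_that("a fitted model survives JSON serialization", {
  d <- simulate_panel(two_class_config(seed = 6, delta = rep(0.3, 6)))
  fit <- fit_lca(d, 2, n_starts = 4, start_iters = 30, seed = 5)
  tmp <- tempfile(fileext = ".json")
  write_lca_fit(fit, tmp)
  back <- read_lca_fit(tmp)
  expect_equal(back$measurement$beta0, fit$measurement$beta0,
               tolerance = 1e-12)
  expect_equal(back$measurement$delta, fit$measurement$delta,
               tolerance = 1e-12)
  expect_equal(back$weights, fit$weights, tolerance = 1e-12)
  expect_equal(class_log_densities(back, d), class_log_densities(fit, d),
               tolerance = 1e-12)
})

test_that("degenerate inputs are rejected or flagged", {
  d <- simulate_pooled(two_class_config(seed = 2), 50)
  dd <- as.data.frame(d)
  dd$mdd[3] <- NA
  expect_error(as_panel(dd, indicators = attr(d, "indicators")), "missing")
  expect_warning(fit_lca(d, 40, n_starts = 2, start_iters = 10, seed = 1),
                 "patterns")
  expect_error(fit_lca(d[0, ], 2), "empty")
})
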