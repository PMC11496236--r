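test_that("generator configuration validation names the offending field", {
  expect_error(generator_config(pi0 = c(0.5, 0.4)), "pi0")
  expect_error(generator_config(A = matrix(1, 4, 3)), "'A'")
  E <- default_emissions(); E[1, 1] <- 1.2
  expect_error(generator_config(emissions = E), "emissions")
  expect_error(generator_config(baseline_delta = rep(-1, 8)), "baseline_delta")
  expect_error(generator_config(n_waves = 1), "n_waves")
  expect_error(generator_config(retention = c(0.5, 0.5)), "retention")
})

test_that("degenerate emissions and absorbing dynamics behave exactly", {
  K1 <- generator_config(n_individuals = 50, n_waves = 2,
                         pi0 = 1, A = matrix(1, 1, 1),
                         emissions = matrix(0, 1, 4,
                           dimnames = list(NULL, lc_indicators()[1:4])),
                         baseline_delta = rep(0, 4), retention = 1,
                         dropout = "none", seed = 3)
  d <- simulate_panel(K1)
  expect_true(all(lcpanel:::panel_matrix(d) == 0))

  ident <- generator_config(n_individuals = 100, n_waves = 4,
                            A = diag(4), dropout = "none",
                            baseline_delta = rep(0, 8), seed = 5)
  d2 <- simulate_panel(ident)
  per <- tapply(d2$latent_class_truth, d2$person_id,
                function(z) length(unique(z)))
  expect_true(all(per == 1))
})

test_that("default attrition reproduces the observed wave sizes and 20574 records", {
  expect_equal(expected_records(generator_config()), 20574)
  d <- simulate_panel(generator_config(seed = 17))
  expect_identical(as.integer(table(d$wave)), c(6646L, 5303L, 4618L, 4007L))
  expect_identical(nrow(d), 20574L)
  ## monotone dropout: waves form a prefix for every person
  expect_length(lcpanel:::check_monotone(d), 0)
})

test_that("simulated latent transitions agree with the configured matrix", {
  cfg <- generator_config(n_individuals = 4000, seed = 23)
  d <- simulate_panel(cfg)
  emp <- truth_transitions(d, 4)
  counts <- table(factor(d$latent_class_truth[d$wave < 3], 1:4))
  for (r in 1:2) {  # common rows have enough transitions for tight SEs
    n_r <- sum(emp[r, ] >= 0) * 0 + as.numeric(counts[r])
    se <- sqrt(default_transitions()[r, ] *
                 (1 - default_transitions()[r, ]) / n_r)
    expect_true(all(abs(emp[r, ] - default_transitions()[r, ]) <= 3 * se + 1e-9))
  }
})

test_that("simulation is byte-identical under the same seed", {
  cfg <- generator_config(n_individuals = 300, seed = 11)
  expect_identical(simulate_panel(cfg), simulate_panel(cfg))
  expect_identical(simulate_pooled(cfg, 500), simulate_pooled(cfg, 500))
})

test_that("pooled mode matches the configured mixing proportions", {
  d <- simulate_pooled(generator_config(seed = 31), 20574)
  p1 <- mean(d$latent_class_truth == 1)
  tr <- default_prevalences()[1]
  expect_lt(abs(p1 - tr), 3 * sqrt(tr * (1 - tr) / 20574))
  one <- generator_config(n_individuals = 10, n_waves = 2,
                          pi0 = c(1, 0, 0, 0), retention = 1, seed = 1)
  expect_true(all(simulate_pooled(one, 200)$latent_class_truth == 1))
  expect_error(simulate_pooled(generator_config(), 0), "n_records")
})

test_that("baseline offset raises wave-0 prevalence only", {
  cfg <- generator_config(n_individuals = 20000, n_waves = 2, retention = 1,
                          dropout = "none", seed = 41)
  d <- simulate_panel(cfg)
  Y <- lcpanel:::panel_matrix(d)
  isb <- d$wave == 0
  marg_true <- as.numeric(default_prevalences() %*% default_emissions())
  p_follow <- colMeans(Y[!isb, ])
  se <- sqrt(marg_true * (1 - marg_true) / sum(!isb))
  expect_true(all(abs(p_follow - marg_true) < 4 * se + 1e-9))
  ## delta = 0.5 > 0 on every indicator: baseline strictly higher
  expect_true(all(colMeans(Y[isb, ]) > p_follow - 2 * se))
  expect_gt(mean(colMeans(Y[isb, ]) - p_follow), 0)
})

test_that("attached covariates follow their class-conditional law", {
  cfg <- generator_config(
    n_individuals = 3000, seed = 13,
    covariate_spec = list(
      covariate_spec("flat", "binary", prob = rep(0.5, 4)),
      covariate_spec("sexf", "binary", prob = c(0.45, 0.55, 0.80, 0.55),
                     time_varying = FALSE),
      covariate_spec("bmi", "normal", mean = c(25, 25.5, 26, 26.5), sd = 4)))
  d <- simulate_panel(generator_config(n_individuals = 3000, seed = 13))
  d <- attach_covariates(d, cfg)
  expect_false(anyNA(d$sexf))  # missing rate 0
  ## class-3 female share highest among classes
  m <- tapply(d$sexf, d$latent_class_truth, mean)
  expect_equal(as.integer(which.max(m)), 3L)
  ## class-invariant covariate: no detectable association
  p <- stats::chisq.test(table(d$flat, d$latent_class_truth == 1))$p.value
  expect_gt(p, 0.001)
  ## time-fixed covariate constant within person
  expect_true(all(tapply(d$sexf, d$person_id,
                         function(v) length(unique(v))) == 1))
  expect_error(attach_covariates(d, generator_config()), "covariate_spec")
})
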