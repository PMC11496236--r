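make_cov_cohort <- function(n = 2000L, seed = 1L, shift = TRUE,
                            n_waves = 2L) {
  E <- rbind(c(0.05, 0.05, 0.10, 0.05, 0.10, 0.05),
             c(0.80, 0.70, 0.60, 0.75, 0.65, 0.70))
  colnames(E) <- lc_indicators()[1:6]
  prob <- if (shift) c(0.40, 0.75) else c(0.5, 0.5)
  generator_config(n_individuals = n, n_waves = n_waves,
                   pi0 = c(0.7, 0.3),
                   A = rbind(c(0.9, 0.1), c(0.2, 0.8)),
                   emissions = E, baseline_delta = rep(0, 6),
                   retention = rep(1, n_waves - 1L), dropout = "none",
                   covariate_spec = list(
                     covariate_spec("xv", "binary", prob = prob)),
                   seed = seed)
}

test_that("class profiles recover class-conditional covariate means", {
  cfg <- make_cov_cohort(n = 4000, seed = 5)
  d <- simulate_panel(cfg)
  fit <- fit_lca(d, 2, n_starts = 8, start_iters = 50, seed = 2)
  perm <- match_classes(emission_probs(fit$measurement),
                        cfg$emissions)
  pc <- profile_classes(fit, d, "xv")
  est <- pc$profiles$estimate[perm]
  expect_lt(abs(est[1] - 0.40), 0.03)
  expect_lt(abs(est[2] - 0.75), 0.04)
  expect_lt(pc$tests$p, 1e-6)
  expect_equal(pc$tests$df, 1)
  expect_equal(pc$tests$n_used, nrow(d))
})

test_that("profile Wald test holds its nominal size under the null", {
  rej <- vapply(1:60, function(r) {
    cfg <- make_cov_cohort(n = 700, seed = 3000 + r, shift = FALSE)
    d <- simulate_panel(cfg)
    fit <- fit_lca(d, 2, n_starts = 6, start_iters = 40, seed = r)
    profile_classes(fit, d, "xv")$tests$p < 0.05
  }, logical(1))
  ## binomial band around 0.05 for 60 replicates
  expect_lt(abs(mean(rej) - 0.05), 2 * sqrt(0.05 * 0.95 / 60) + 1e-9)
})

test_that("profiles drop missing covariate records and handle degenerate input", {
  cfg <- make_cov_cohort(n = 500, seed = 9)
  d <- simulate_panel(cfg)
  d$xv[1:100] <- NA
  fit <- fit_lca(d, 2, n_starts = 4, start_iters = 30, seed = 2)
  pc <- profile_classes(fit, d, "xv")
  expect_equal(pc$tests$n_used, nrow(d) - 100)
  ## constant covariate: equality test undefined, reported as NA
  d$const <- 1
  pc2 <- profile_classes(fit, d, "const")
  expect_true(is.na(pc2$tests$wald))
  ## K = 1: single overall mean, no test
  f1 <- fit_lca(d, 1, n_starts = 1, start_iters = 5, seed = 1)
  pc3 <- profile_classes(f1, d, "xv")
  expect_equal(nrow(pc3$profiles), 1)
  expect_true(is.na(pc3$tests$p))
})

test_that("an injected transition effect is recovered with the right sign", {
  E <- rbind(c(0.05, 0.05, 0.10, 0.05, 0.10, 0.05),
             c(0.80, 0.70, 0.60, 0.75, 0.65, 0.70))
  colnames(E) <- lc_indicators()[1:6]
  tc <- matrix(0, 2, 2); tc[1, 2] <- 1.2
  cfg <- generator_config(n_individuals = 4000, n_waves = 3,
                          pi0 = c(0.7, 0.3),
                          A = rbind(c(0.9, 0.1), c(0.2, 0.8)),
                          emissions = E, baseline_delta = rep(0, 6),
                          retention = c(1, 1), dropout = "none",
                          covariate_spec = list(
                            covariate_spec("xv", "binary",
                                           prob = c(0.4, 0.4),
                                           trans_coef = tc)),
                          seed = 8)
  d <- simulate_panel(cfg)
  fit <- fit_lca(d, 2, n_starts = 8, start_iters = 50, seed = 3)
  tl <- transition_logit(fit, d, "xv")
  row12 <- tl$table[tl$table$origin == "class1" &
                      tl$table$destination == "class2", ]
  expect_gt(row12$estimate, 0.5)
  expect_lt(row12$p, 0.001)
  expect_true(row12$flag_001 && row12$flag_01)
  expect_equal(row12$direction, "unfavorable")
})

test_that("zero-slope model matches the covariate-free Markov fit", {
  cfg <- make_cov_cohort(n = 1500, seed = 12, n_waves = 3L)
  d <- simulate_panel(cfg)
  fit <- fit_lca(d, 2, n_starts = 8, start_iters = 50, seed = 4)
  mk <- fit_latent_markov(d, fit, se = FALSE)
  tl0 <- transition_logit(fit, d, "xv", null_slopes = TRUE, se = FALSE)
  expect_lt(max(abs(tl0$implied_A - mk$A)), 1e-4)
  expect_lt(max(abs(tl0$pi0 - mk$pi0)), 1e-4)
})

test_that("mean imputation preserves the covariate mean exactly", {
  cfg <- make_cov_cohort(n = 400, seed = 14)
  cfg$covariate_spec[[1]]$missing_rate <- 0.2
  d <- simulate_panel(cfg)
  expect_gt(sum(is.na(d$xv)), 0)
  x <- d$xv
  xbar <- mean(x, na.rm = TRUE)
  x[is.na(x)] <- xbar
  expect_identical(mean(x), xbar)
})

test_that("Wald statistics are invariant to affine covariate rescaling", {
  cfg <- make_cov_cohort(n = 1200, seed = 20, n_waves = 3L)
  d <- simulate_panel(cfg)
  fit <- fit_lca(d, 2, n_starts = 8, start_iters = 50, seed = 4)
  tl <- transition_logit(fit, d, "xv")
  d$xs <- 10 * d$xv - 3
  tls <- transition_logit(fit, d, "xs")
  expect_equal(tls$table$wald, tl$table$wald, tolerance = 1e-3)
})

test_that("a constant covariate triggers the non-estimable error path", {
  cfg <- make_cov_cohort(n = 300, seed = 25)
  d <- simulate_panel(cfg)
  d$allsame <- 2
  fit <- fit_lca(d, 2, n_starts = 4, start_iters = 30, seed = 1)
  expect_error(transition_logit(fit, d, "allsame"), "non-estimable")
})
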