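# model choice and diagnostics: information criteria, parametric bootstrap
# tests, bivariate residuals, design effect

#' Information criteria for a latent class fit
#'
#' `AIC = -2 logL + 2p`, `AIC3 = -2 logL + 3p` (penalty factor 3) and
#' `BIC = -2 logL + p log(n)`; for all three the smallest value is preferred.
#' `n` is the number of pooled records by default (each wave is a case in the
#' measurement step); set `n_scale = "persons"` to penalize by respondents
#' instead.
#'
#' @param fit an [fit_lca()] result.
#' @param n_scale `"records"` (default) or `"persons"`.
#' @return Named list with `AIC`, `BIC`, `AIC3`.
#' @export
information_criteria <- function(fit, n_scale = c("records", "persons")) {
  n_scale <- match.arg(n_scale)
  n <- if (n_scale == "records") fit$n_records else fit$n_persons
  if (n < 2L) stop("information criteria need at least 2 observations")
  p <- fit$n_params
  list(AIC = -2 * fit$loglik + 2 * p,
       BIC = -2 * fit$loglik + p * log(n),
       AIC3 = -2 * fit$loglik + 3 * p)
}

## parametric simulation from a fitted latent class model, preserving the
## record count and baseline flag composition of a template dataset
simulate_from_lca <- function(fit, data, seed) {
  meas <- fit$measurement
  isb <- data$wave == 0L
  n <- nrow(data)
  with_seed(seed, {
    z <- sample.int(fit$K, n, replace = TRUE, prob = fit$weights)
    P_f <- emission_probs(meas, FALSE)
    P_b <- emission_probs(meas, TRUE)
    P <- P_f[z, , drop = FALSE]
    if (any(isb)) P[isb, ] <- P_b[z[isb], , drop = FALSE]
    Y <- matrix(stats::rbinom(length(P), 1L, P), n, meas$J)
    colnames(Y) <- fit$indicators
    out <- data.frame(person_id = seq_len(n), wave = as.integer(isb == FALSE))
    out$wave <- ifelse(isb, 0L, 1L)
    out <- cbind(out, as.data.frame(Y))
    out$latent_class_truth <- z
    as_panel(out, indicators = fit$indicators)
  })
}

## likelihood-ratio goodness-of-fit statistic over response patterns,
## stratified by the baseline flag
l2_statistic <- function(fit, data) {
  Y <- panel_matrix(data)
  isb <- data$wave == 0L
  pp <- pool_patterns(Y, isb)
  pat <- as_panel(data.frame(person_id = seq_len(nrow(pp$Y)),
                             wave = ifelse(pp$bf == 1L, 0L, 1L),
                             as.data.frame(pp$Y)),
                  indicators = colnames(Y))
  LD <- class_log_densities(fit, pat)
  lp <- apply(sweep(LD, 2L, log(fit$weights + 1e-300), `+`), 1L, logsumexp)
  n_flag <- c(sum(!isb), sum(isb))
  expected <- n_flag[pp$bf + 1L] * exp(lp)
  2 * sum(pp$w * log(pp$w / pmax(expected, 1e-300)))
}

#' Parametric bootstrap goodness-of-fit test
#'
#' Likelihood-ratio goodness-of-fit statistic (L-squared over response
#' patterns, stratified by baseline flag) with a bootstrap p value: `B`
#' datasets are simulated from the fitted model (matching record count and
#' baseline flags), the same-K model is refitted to each with a reduced
#' multi-start budget, and `p = (1 + #{L2_b >= L2_obs}) / (B + 1)`.
#'
#' @param fit an [fit_lca()] result.
#' @param data the dataset the fit was obtained from.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param refit_starts,refit_iters,refit_max_iter multi-start budget per
#'   bootstrap refit (default 8 starts of 50 iterations, then continuation).
#' @return List with `p_value`, `statistic`, `boot_stats`.
#' @export
bootstrap_gof <- function(fit, data, B = 99L, seed = 1L, refit_starts = 8L,
                          refit_iters = 50L, refit_max_iter = 500L) {
  if (B < 1L) stop("B must be >= 1")
  obs <- l2_statistic(fit, data)
  stats_b <- numeric(B)
  for (b in seq_len(B)) {
    sim <- simulate_from_lca(fit, data, seed = derive_seed(seed, "gof", b))
    refit <- fit_lca(sim, fit$K, n_starts = refit_starts,
                     start_iters = refit_iters, max_iter = refit_max_iter,
                     tol = 1e-6, seed = derive_seed(seed, "gof-start", b),
                     baseline_effect = fit$baseline_effect)
    stats_b[b] <- l2_statistic(refit, sim)
  }
  list(p_value = (1 + sum(stats_b >= obs)) / (B + 1),
       statistic = obs, boot_stats = stats_b)
}

#' Bootstrap likelihood-ratio test for K versus K-1 classes
#'
#' Statistic `-2 (logL_{K-1} - logL_K)`; the null distribution is generated
#' by a parametric bootstrap under the fitted (K-1)-class model, refitting
#' both models to each simulated dataset with a reduced multi-start budget.
#' The p value uses the add-one rule and never equals zero. Non-convergent
#' bootstrap replicates are excluded (with a hard error if more than 20%
#' are lost).
#'
#' @param data an [as_panel()] dataset.
#' @param K alternative number of classes (>= 2).
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param n_starts,start_iters multi-start budget for the two observed-data
#'   fits.
#' @param refit_starts,refit_iters budget per bootstrap refit.
#' @return List with `p_value`, `statistic`, `boot_stats`, `n_excluded`,
#'   and the two observed-data fits.
#' @export
bootstrap_lrt <- function(data, K, B = 49L, seed = 1L, n_starts = 16L,
                          start_iters = 100L, refit_starts = 8L,
                          refit_iters = 50L) {
  if (K < 2L) stop("K must be >= 2")
  fit0 <- fit_lca(data, K - 1L, n_starts = n_starts, start_iters = start_iters,
                  seed = derive_seed(seed, "lrt-null"))
  fit1 <- fit_lca(data, K, n_starts = n_starts, start_iters = start_iters,
                  seed = derive_seed(seed, "lrt-alt"))
  obs <- -2 * (fit0$loglik - fit1$loglik)
  stats_b <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    sim <- simulate_from_lca(fit0, data, seed = derive_seed(seed, "lrt", b))
    r0 <- fit_lca(sim, K - 1L, n_starts = refit_starts,
                  start_iters = refit_iters, max_iter = 500L, tol = 1e-6,
                  seed = derive_seed(seed, "lrt-s0", b),
                  baseline_effect = fit0$baseline_effect)
    r1 <- fit_lca(sim, K, n_starts = refit_starts,
                  start_iters = refit_iters, max_iter = 500L, tol = 1e-6,
                  seed = derive_seed(seed, "lrt-s1", b),
                  baseline_effect = fit0$baseline_effect)
    if (r0$converged && r1$converged) {
      stats_b[b] <- -2 * (r0$loglik - r1$loglik)
    }
  }
  n_excl <- sum(is.na(stats_b))
  if (n_excl > 0.2 * B) {
    stop(n_excl, " of ", B, " bootstrap replicates failed to converge")
  }
  ok <- stats_b[!is.na(stats_b)]
  list(p_value = (1 + sum(ok >= obs)) / (length(ok) + 1),
       statistic = obs, boot_stats = ok, n_excluded = n_excl,
       fit_null = fit0, fit_alt = fit1)
}

#' Bivariate residuals
#'
#' For every indicator pair (and optionally every extra variable x indicator
#' pair, e.g. the wave number coded 0-3), a Pearson X-squared statistic
#' comparing the observed two-way table to the model-expected table, divided
#' by the table's degrees of freedom. Expected tables are built from the
#' posterior-weighted class composition and the class-specific response
#' probabilities (baseline offset honored at wave 0). Values below 3-4
#' indicate adequately captured pairwise association; residuals of external
#' variables (like the wave) below 1 indicate time-invariant classes.
#'
#' @param fit an [fit_lca()] result.
#' @param data the dataset the fit was obtained from.
#' @param extra_vars optional character vector of column names (categorical)
#'   to cross with each indicator.
#' @return Data frame with columns `var1`, `var2`, `bvr`, `df`, `flagged`
#'   (whether any expected cell was clipped).
#' @export
bivariate_residuals <- function(fit, data, extra_vars = NULL) {
  Y <- panel_matrix(data)
  J <- ncol(Y)
  isb <- data$wave == 0L
  post <- posterior_classes(fit, data)
  P_f <- emission_probs(fit$measurement, FALSE)
  P_b <- emission_probs(fit$measurement, TRUE)
  ## posterior mass per (flag, class)
  S <- rbind(colSums(post[!isb, , drop = FALSE]),
             colSums(post[isb, , drop = FALSE]))  # 2 x K
  rows <- list()
  flagged <- FALSE
  cell <- function(O, E) {
    flag <- any(E < 1e-12)
    E <- pmax(E, 1e-12)
    list(x2 = sum((O - E)^2 / E), flag = flag)
  }
  for (j in seq_len(J - 1L)) {
    for (jj in (j + 1L):J) {
      O11 <- sum(Y[, j] * Y[, jj]); O10 <- sum(Y[, j] * (1 - Y[, jj]))
      O01 <- sum((1 - Y[, j]) * Y[, jj]); O00 <- nrow(Y) - O11 - O10 - O01
      E11 <- sum(S[1, ] * P_f[, j] * P_f[, jj]) + sum(S[2, ] * P_b[, j] * P_b[, jj])
      E10 <- sum(S[1, ] * P_f[, j] * (1 - P_f[, jj])) + sum(S[2, ] * P_b[, j] * (1 - P_b[, jj]))
      E01 <- sum(S[1, ] * (1 - P_f[, j]) * P_f[, jj]) + sum(S[2, ] * (1 - P_b[, j]) * P_b[, jj])
      E00 <- sum(S[1, ] * (1 - P_f[, j]) * (1 - P_f[, jj])) + sum(S[2, ] * (1 - P_b[, j]) * (1 - P_b[, jj]))
      cc <- cell(c(O11, O10, O01, O00), c(E11, E10, E01, E00))
      rows[[length(rows) + 1L]] <- data.frame(
        var1 = colnames(Y)[j], var2 = colnames(Y)[jj],
        bvr = cc$x2 / 1, df = 1L, flagged = cc$flag)
    }
  }
  for (v in extra_vars %||% character(0)) {
    lv <- sort(unique(data[[v]]))
    if (length(lv) < 2L) next
    for (j in seq_len(J)) {
      O <- E <- matrix(0, length(lv), 2L)
      for (li in seq_along(lv)) {
        sel <- data[[v]] == lv[li]
        O[li, 1L] <- sum(Y[sel, j]); O[li, 2L] <- sum(sel) - O[li, 1L]
        Sf <- colSums(post[sel & !isb, , drop = FALSE])
        Sb <- colSums(post[sel & isb, , drop = FALSE])
        E[li, 1L] <- sum(Sf * P_f[, j]) + sum(Sb * P_b[, j])
        E[li, 2L] <- sum(Sf * (1 - P_f[, j])) + sum(Sb * (1 - P_b[, j]))
      }
      dfree <- (length(lv) - 1L)
      cc <- cell(as.vector(O), as.vector(E))
      rows[[length(rows) + 1L]] <- data.frame(
        var1 = v, var2 = colnames(Y)[j],
        bvr = cc$x2 / dfree, df = dfree, flagged = cc$flag)
    }
  }
  do.call(rbind, rows)
}

#' Design effect of within-person clustering on the class proportions
#'
#' Ratio of the cluster-robust (sandwich, clustered on person) to the naive
#' variance of the estimated class-proportion parameters, averaged over the
#' K-1 free proportions. A value close to 1 justifies treating pooled
#' person-waves as independent in the measurement step.
#'
#' @param data an [as_panel()] dataset.
#' @param fit an [fit_lca()] result on that data.
#' @param cluster column name identifying the primary sampling unit.
#' @return Scalar design effect (exactly 1 when every cluster contributes a
#'   single record).
#' @export
design_effect <- function(data, fit, cluster = "person_id") {
  if (fit$K < 2L) stop("design effect needs K >= 2 free proportions")
  cl <- data[[cluster]]
  if (length(unique(cl)) < 2L) stop("need at least 2 clusters")
  post <- posterior_classes(fit, data)
  s <- sweep(post[, -1L, drop = FALSE], 2L, fit$weights[-1L], `-`)
  H <- crossprod(s)
  G <- rowsum(s, cl)
  meat <- crossprod(G)
  Hi <- solve(H)
  robust <- Hi %*% meat %*% Hi
  naive <- Hi
  mean(diag(robust) / diag(naive))
}

#' Explore the number of latent classes
#'
#' Fits latent class models over a range of K and tabulates log-likelihood,
#' information criteria, optional bootstrap p values and the maximum
#' bivariate residual. `chosen_K` minimizes BIC (with AIC3 shown for
#' comparison; the final choice should also weigh interpretability).
#'
#' @param data an [as_panel()] dataset.
#' @param k_min,k_max range of class counts.
#' @param n_starts,start_iters multi-start budget per fit.
#' @param gof_B,lrt_B bootstrap replicates for the goodness-of-fit and
#'   likelihood-ratio tests (0 skips them).
#' @param seed integer seed.
#' @return Data frame of class `selection_report`, one row per K, with the
#'   fits attached as an attribute and `chosen_K` as an attribute.
#' @export
select_k <- function(data, k_min = 1L, k_max = 5L, n_starts = 16L,
                     start_iters = 100L, gof_B = 0L, lrt_B = 0L, seed = 1L) {
  ks <- seq.int(k_min, k_max)
  fits <- lapply(ks, function(k) {
    fit_lca(data, k, n_starts = n_starts, start_iters = start_iters,
            seed = derive_seed(seed, "select", k))
  })
  rows <- lapply(seq_along(ks), function(i) {
    fit <- fits[[i]]
    ic <- information_criteria(fit)
    bvr <- bivariate_residuals(fit, data)
    gof_p <- if (gof_B > 0)
      bootstrap_gof(fit, data, B = gof_B,
                    seed = derive_seed(seed, "gof", ks[i]))$p_value else NA_real_
    lrt_p <- if (lrt_B > 0 && ks[i] > k_min)
      bootstrap_lrt(data, ks[i], B = lrt_B, n_starts = n_starts,
                    start_iters = start_iters,
                    seed = derive_seed(seed, "lrt", ks[i]))$p_value else NA_real_
    data.frame(K = ks[i], loglik = fit$loglik, n_params = fit$n_params,
               BIC = ic$BIC, AIC = ic$AIC, AIC3 = ic$AIC3,
               bootstrap_gof_p = gof_p, bootstrap_lrt_p = lrt_p,
               max_BVR = max(bvr$bvr))
  })
  rep <- do.call(rbind, rows)
  attr(rep, "fits") <- fits
  attr(rep, "chosen_K") <- rep$K[which.min(rep$BIC)]
  class(rep) <- c("selection_report", "data.frame")
  rep
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Latent class model selection\n")
  df <- as.data.frame(x)
  df$loglik <- round(df$loglik, 2)
  for (cc in c("BIC", "AIC", "AIC3", "max_BVR")) df[[cc]] <- round(df[[cc]], 2)
  print(df, row.names = FALSE)
  cat("chosen K (min BIC):", attr(x, "chosen_K"), "\n")
  invisible(x)
}
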