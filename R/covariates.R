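# class profiling by background characteristics and covariate effects on
# latent transitions, both under the two-step scheme (measurement frozen)

#' Profile latent classes by background characteristics
#'
#' Two-step class description: with the measurement model fixed, class-
#' specific covariate means (proportions for binary covariates) are estimated
#' by posterior-weighted averaging over all pooled records, and an overall
#' Wald test of equality across classes is computed with variance clustered
#' on person (accounting for dependencies between waves). Records with a
#' missing covariate are dropped for that covariate only.
#'
#' @param fit an [fit_lca()] result.
#' @param data an [as_panel()] dataset containing the covariates.
#' @param covariate_names character vector of covariate columns.
#' @return Object of class `covariate_profiles`: list with `profiles`
#'   (covariate x class estimates and cluster-robust SEs, tidy) and `tests`
#'   (Wald statistic, df = K-1, p, records used).
#' @export
profile_classes <- function(fit, data, covariate_names) {
  K <- fit$K
  post_all <- posterior_classes(fit, data)
  prof <- list(); tests <- list()
  for (v in covariate_names) {
    if (!v %in% names(data)) stop("covariate not found: ", v)
    x <- data[[v]]
    sel <- !is.na(x)
    x <- as.numeric(x[sel])
    W <- post_all[sel, , drop = FALSE]
    cl <- data$person_id[sel]
    Nw <- colSums(W)
    est <- colSums(W * x) / Nw
    ## cluster-robust variance from the weighted-mean estimating equations
    s <- W * outer(x, rep(1, K)) - sweep(W, 2L, est, `*`)
    G <- rowsum(s, cl)
    V <- diag(1 / Nw, K) %*% crossprod(G) %*% diag(1 / Nw, K)
    se <- sqrt(pmax(diag(V), 0))
    wald <- df <- p <- NA_real_
    if (K >= 2L) {
      if (stats::sd(x) == 0) {
        wald <- NA_real_  # constant covariate: equality test undefined
      } else {
        C <- cbind(-1, diag(K - 1L))
        d <- as.numeric(C %*% est)
        CV <- C %*% V %*% t(C)
        ok <- tryCatch({wald <- as.numeric(t(d) %*% solve(CV, d)); TRUE},
                       error = function(e) FALSE)
        if (ok) { df <- K - 1L; p <- stats::pchisq(wald, df, lower.tail = FALSE) }
      }
    }
    prof[[v]] <- data.frame(covariate = v, class = class_labels(K),
                            estimate = est, se = se, row.names = NULL)
    tests[[v]] <- data.frame(covariate = v, wald = wald, df = df, p = p,
                             n_used = sum(sel), row.names = NULL)
  }
  structure(list(profiles = do.call(rbind, prof),
                 tests = do.call(rbind, tests)),
            class = "covariate_profiles")
}

#' @export
print.covariate_profiles <- function(x, ...) {
  cat("Class profiles (posterior-weighted, cluster-robust SEs)\n")
  pr <- x$profiles
  pr$estimate <- round(pr$estimate, 4); pr$se <- round(pr$se, 4)
  print(pr, row.names = FALSE)
  cat("\nWald tests of class equality\n")
  tt <- x$tests
  tt$wald <- round(tt$wald, 2); tt$p <- signif(tt$p, 3)
  print(tt, row.names = FALSE)
  invisible(x)
}

## per-(person, interval) transition matrices under the multinomial logit
## a[r,k] + b[r,k] * x, staying (k == r) as the reference destination
build_trans_array <- function(a, b, X, K) {
  n <- nrow(X); Tm1 <- ncol(X)
  A <- array(0, c(n, Tm1, K, K))
  for (t in seq_len(Tm1)) {
    for (r in seq_len(K)) {
      eta <- matrix(a[r, ], n, K, byrow = TRUE) +
        X[, t] %o% b[r, ]
      eta[, r] <- 0
      A[, t, r, ] <- softmax_rows(eta)
    }
  }
  A
}

## weighted multinomial-logit Newton step(s) for one origin's parameters
## N: M x K expected destination counts; x: M covariate values
mlogit_newton <- function(a_r, b_r, r, N, x, iters = 3L, fit_slopes = TRUE) {
  K <- ncol(N)
  ks <- setdiff(seq_len(K), r)
  nm <- rowSums(N)
  qfun <- function(a, b) {
    eta <- matrix(a[ks], length(x), K - 1L, byrow = TRUE)
    if (fit_slopes) eta <- eta + x %o% b[ks]
    eta <- cbind(eta, 0)
    lse <- apply(eta, 1L, logsumexp)
    sum(N[, c(ks, r)] * (eta - lse))
  }
  q0 <- qfun(a_r, b_r)
  np <- if (fit_slopes) 2L else 1L
  for (it in seq_len(iters)) {
    eta <- matrix(a_r[ks], length(x), K - 1L, byrow = TRUE)
    if (fit_slopes) eta <- eta + x %o% b_r[ks]
    q <- softmax_rows(cbind(eta, 0))[, seq_len(K - 1L), drop = FALSE]
    resid <- N[, ks, drop = FALSE] - nm * q
    grad <- numeric(np * (K - 1L))
    H <- matrix(0, np * (K - 1L), np * (K - 1L))
    for (ki in seq_len(K - 1L)) {
      ii <- (ki - 1L) * np
      grad[ii + 1L] <- sum(resid[, ki])
      if (fit_slopes) grad[ii + 2L] <- sum(x * resid[, ki])
      for (li in seq_len(K - 1L)) {
        jj <- (li - 1L) * np
        wkl <- nm * q[, ki] * ((ki == li) - q[, li])
        H[ii + 1L, jj + 1L] <- H[ii + 1L, jj + 1L] - sum(wkl)
        if (fit_slopes) {
          H[ii + 1L, jj + 2L] <- H[ii + 1L, jj + 2L] - sum(wkl * x)
          H[ii + 2L, jj + 1L] <- H[ii + 2L, jj + 1L] - sum(wkl * x)
          H[ii + 2L, jj + 2L] <- H[ii + 2L, jj + 2L] - sum(wkl * x^2)
        }
      }
    }
    step <- tryCatch(solve(-H + diag(1e-10, nrow(H)), grad),
                     error = function(e) grad * 0)
    scale <- 1
    for (hh in 1:30) {
      an <- a_r; bn <- b_r
      for (ki in seq_len(K - 1L)) {
        ii <- (ki - 1L) * np
        an[ks[ki]] <- a_r[ks[ki]] + scale * step[ii + 1L]
        if (fit_slopes) bn[ks[ki]] <- b_r[ks[ki]] + scale * step[ii + 2L]
      }
      an <- pmin(pmax(an, -30), 30); bn <- pmin(pmax(bn, -30), 30)
      q1 <- qfun(an, bn)
      if (q1 >= q0 - 1e-12) { a_r <- an; b_r <- bn; q0 <- q1; break }
      scale <- scale / 2
    }
  }
  list(a = a_r, b = b_r)
}

#' Covariate effects on latent transitions
#'
#' Re-estimates the latent Markov model (measurement frozen) with the
#' transition probabilities parameterized by origin-specific multinomial
#' logits in a single covariate measured at time T, predicting the
#' transition to T+1; staying in the origin class is the reference
#' destination. Missing covariate values are mean-imputed before fitting.
#' Wald tests per slope are cluster-robust on person; effects are flagged at
#' both the stricter p < 0.001 level (appropriate for the many tests run one
#' covariate at a time) and at p < 0.01.
#'
#' @param fit an [fit_lca()] result (frozen measurement).
#' @param data an [as_panel()] dataset containing the covariate.
#' @param covariate_name single covariate column name.
#' @param time_varying if `FALSE` (sex, childhood abuse) the wave-0 value is
#'   used at every interval.
#' @param max_iter,tol EM control.
#' @param se compute cluster-robust Wald statistics.
#' @param null_slopes fix all slopes at zero (used to verify equivalence
#'   with the covariate-free Markov fit, and for likelihood comparisons).
#' @param newton_iters inner Newton iterations per M-step.
#' @return Object of class `transition_covariate_result`: data frame `table`
#'   (origin, destination, estimate, se, wald, p, flag_001, flag_01,
#'   direction, estimable) plus `pi0`, `intercepts`, `slopes`, `implied_A`
#'   (at the mean covariate value), `loglik`, `converged`.
#' @export
transition_logit <- function(fit, data, covariate_name, time_varying = TRUE,
                             max_iter = 500L, tol = 1e-8, se = TRUE,
                             null_slopes = FALSE, newton_iters = 3L) {
  bd <- build_ld_array(data, fit)
  if (bd$Tn < 2L) stop("needs at least 2 waves")
  K <- bd$K; n <- bd$n; Tm1 <- bd$Tn - 1L
  ## covariate per (person, wave); mean imputation preserves the mean exactly
  xrec <- as.numeric(data[[covariate_name]])
  xbar <- mean(xrec, na.rm = TRUE)
  if (!is.finite(xbar)) stop("covariate has no observed values")
  xrec[is.na(xrec)] <- xbar
  pidx <- match(data$person_id, bd$ids)
  X <- matrix(xbar, n, bd$Tn)
  X[cbind(pidx, data$wave + 1L)] <- xrec
  if (!time_varying) X <- matrix(X[, 1L], n, bd$Tn)
  X <- X[, seq_len(Tm1), drop = FALSE]  # value at T predicts T -> T+1
  if (stats::sd(as.numeric(X)) == 0 && !null_slopes) {
    stop("covariate '", covariate_name,
         "' is constant after imputation; slopes are non-estimable")
  }

  ## initialize from the covariate-free fit
  mk <- fit_latent_markov(data, fit, se = FALSE)
  pi0 <- as.numeric(mk$pi0)
  a <- log(pmax(mk$A, 1e-8) / pmax(diag(mk$A)[row(mk$A)], 1e-8))
  diag(a) <- 0
  b <- matrix(0, K, K)

  ll_prev <- -Inf; converged <- FALSE; iter <- 0L
  repeat {
    iter <- iter + 1L
    Aarr <- build_trans_array(a, b, X, K)
    eng <- fb_engine(pi0, Aarr, bd$LB, bd$lastT, keep_xi = TRUE)
    ll <- sum(eng$loglik)
    pi0 <- colMeans(eng$gamma1)
    for (r in seq_len(K)) {
      ## flatten expected transition counts over (person, interval)
      N <- matrix(aperm(eng$xi_full[, , r, , drop = FALSE], c(1, 2, 4, 3)),
                  n * Tm1, K)
      xv <- as.numeric(X)
      keep <- rowSums(N) > 1e-12
      if (!any(keep)) next
      upd <- mlogit_newton(a[r, ], b[r, ], r, N[keep, , drop = FALSE],
                           xv[keep], iters = newton_iters,
                           fit_slopes = !null_slopes)
      a[r, ] <- upd$a; b[r, ] <- upd$b
    }
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-12)) {
      converged <- TRUE; break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
  }
  if (!converged) warning("transition-covariate EM did not converge")

  ## informative transitions per origin (expected counts)
  Aarr <- build_trans_array(a, b, X, K)
  eng <- fb_engine(pi0, Aarr, bd$LB, bd$lastT, keep_xi = TRUE)
  ll <- sum(eng$loglik)
  origin_n <- apply(eng$xi_person, 2L, sum)
  estimable <- origin_n >= 2

  ## cluster-robust sandwich on (pi0 logits, intercepts, slopes)
  SE <- matrix(NA_real_, K, K)
  if (se && !null_slopes) {
    sw <- translogit_sandwich(pi0, a, b, X, bd)
    SE <- sw$se_b
  }

  lbl <- class_labels(K)
  rows <- list()
  for (r in seq_len(K)) for (k in seq_len(K)) {
    if (k == r) next
    est <- if (estimable[r]) b[r, k] else NA_real_
    sev <- if (estimable[r]) SE[r, k] else NA_real_
    wald <- if (!is.na(est) && !is.na(sev) && sev > 0) (est / sev)^2 else NA_real_
    p <- if (!is.na(wald)) stats::pchisq(wald, 1L, lower.tail = FALSE) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = covariate_name, origin = lbl[r], destination = lbl[k],
      estimate = est, se = sev, wald = wald, p = p,
      flag_001 = isTRUE(p < 0.001), flag_01 = isTRUE(p < 0.01),
      direction = if (k < r) "favorable" else "unfavorable",
      estimable = estimable[r], row.names = NULL)
  }
  xm <- mean(X)
  implied <- t(vapply(seq_len(K), function(r) {
    eta <- a[r, ] + if (null_slopes) 0 else b[r, ] * xm
    eta[r] <- 0
    softmax(eta)
  }, numeric(K)))
  dimnames(implied) <- list(lbl, lbl)
  structure(list(table = do.call(rbind, rows), pi0 = pi0, intercepts = a,
                 slopes = b, implied_A = implied, loglik = ll,
                 converged = converged, n_iter = iter,
                 origin_transitions = origin_n),
            class = "transition_covariate_result")
}

#' @export
print.transition_covariate_result <- function(x, ...) {
  cat("Covariate effects on latent transitions (stay = reference)\n")
  tb <- x$table
  for (cc in c("estimate", "se", "wald")) tb[[cc]] <- round(tb[[cc]], 3)
  tb$p <- signif(tb$p, 3)
  print(tb, row.names = FALSE)
  cat(sprintf("\nlogLik = %.3f (%sconverged)\n", x$loglik,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

## analytic per-person scores for the covariate-Markov parameters
translogit_scores <- function(theta, X, bd) {
  K <- bd$K; n <- bd$n; Tm1 <- ncol(X)
  pi0 <- theta_to_pi(theta[seq_len(K - 1L)])
  a <- matrix(0, K, K); b <- matrix(0, K, K)
  i <- K - 1L
  for (r in seq_len(K)) for (k in seq_len(K)) {
    if (k == r) next
    a[r, k] <- theta[i + 1L]; b[r, k] <- theta[i + 2L]; i <- i + 2L
  }
  Aarr <- build_trans_array(a, b, X, K)
  eng <- fb_engine(pi0, Aarr, bd$LB, bd$lastT, keep_xi = TRUE)
  G <- matrix(0, n, length(theta))
  G[, seq_len(K - 1L)] <- eng$gamma1[, -1L, drop = FALSE] -
    matrix(pi0[-1L], n, K - 1L, byrow = TRUE)
  col <- K - 1L
  for (r in seq_len(K)) {
    gam_r <- matrix(0, n, Tm1)  # masked origin marginal per interval
    for (t in seq_len(Tm1)) gam_r[, t] <- rowSums(matrix(eng$xi_full[, t, r, ], n, K))
    for (k in seq_len(K)) {
      if (k == r) next
      sa <- numeric(n); sb <- numeric(n)
      for (t in seq_len(Tm1)) {
        d <- eng$xi_full[, t, r, k] - gam_r[, t] * Aarr[, t, r, k]
        sa <- sa + d
        sb <- sb + X[, t] * d
      }
      G[, col + 1L] <- sa; G[, col + 2L] <- sb
      col <- col + 2L
    }
  }
  G
}

translogit_sandwich <- function(pi0, a, b, X, bd, h = 1e-5) {
  K <- bd$K
  theta <- c(pi_to_theta(pi0))
  for (r in seq_len(K)) for (k in seq_len(K)) {
    if (k == r) next
    theta <- c(theta, pmin(pmax(a[r, k], -30), 30), pmin(pmax(b[r, k], -30), 30))
  }
  P <- length(theta)
  Sc <- translogit_scores(theta, X, bd)
  meat <- crossprod(Sc)
  H <- matrix(0, P, P)
  for (p in seq_len(P)) {
    tp <- theta; tp[p] <- tp[p] + h
    tm <- theta; tm[p] <- tm[p] - h
    H[, p] <- (colSums(translogit_scores(tp, X, bd)) -
               colSums(translogit_scores(tm, X, bd))) / (2 * h)
  }
  info <- -(H + t(H)) / 2
  Vi <- tryCatch(solve(info), error = function(e) MASS_ginv(info))
  V <- Vi %*% meat %*% t(Vi)
  se_b <- matrix(NA_real_, K, K)
  i <- K - 1L
  for (r in seq_len(K)) for (k in seq_len(K)) {
    if (k == r) next
    se_b[r, k] <- sqrt(max(V[i + 2L, i + 2L], 0))
    i <- i + 2L
  }
  list(se_b = se_b, V = V)
}
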