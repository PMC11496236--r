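# step-2 latent Markov (latent transition) model with fixed measurement

## scaled forward-backward over all persons at once.
## LB: n x T x K log emission densities (0 for unobserved waves);
## lastT: last observed wave index + 1 per person (mask for transitions);
## A: K x K shared matrix, or n x (T-1) x K x K per person-interval;
## xw: optional n x (T-1) weight matrix (e.g. covariate values) for weighted
## pairwise-posterior sums.
fb_engine <- function(pi0, A, LB, lastT, xw = NULL, keep_xi = FALSE) {
  dm <- dim(LB); n <- dm[1]; Tn <- dm[2]; K <- dm[3]
  shared <- is.matrix(A)
  B <- exp(LB)
  alph <- array(0, c(n, Tn, K))
  cs <- matrix(0, n, Tn)
  a <- sweep(matrix(B[, 1L, ], n, K), 2L, pi0, `*`)
  cs[, 1L] <- rowSums(a)
  alph[, 1L, ] <- a / cs[, 1L]
  for (t in 2:Tn) {
    ap <- matrix(alph[, t - 1L, ], n, K)
    if (shared) {
      pred <- ap %*% A
    } else {
      pred <- matrix(0, n, K)
      for (r in seq_len(K)) pred <- pred + ap[, r] * matrix(A[, t - 1L, r, ], n, K)
    }
    at <- pred * matrix(B[, t, ], n, K)
    cs[, t] <- rowSums(at)
    alph[, t, ] <- at / cs[, t]
  }
  loglik <- rowSums(log(cs))

  bt <- matrix(1, n, K)
  xi_person <- array(0, c(n, K, K))
  xiw_person <- if (!is.null(xw)) array(0, c(n, K, K)) else NULL
  xi_full <- if (keep_xi) array(0, c(n, Tn - 1L, K, K)) else NULL
  for (t in (Tn - 1L):1L) {
    bb <- matrix(B[, t + 1L, ], n, K) * bt
    ct1 <- cs[, t + 1L]
    infm <- as.numeric(lastT > t)  # transition t -> t+1 observed?
    for (r in seq_len(K)) {
      Ar <- if (shared) matrix(A[r, ], n, K, byrow = TRUE) else matrix(A[, t, r, ], n, K)
      xi_r <- (alph[, t, r] / ct1) * (bb * Ar)
      xi_person[, r, ] <- xi_person[, r, ] + infm * xi_r
      if (!is.null(xw)) xiw_person[, r, ] <- xiw_person[, r, ] + infm * xw[, t] * xi_r
      if (keep_xi) xi_full[, t, r, ] <- infm * xi_r
    }
    if (shared) {
      bt <- (bb %*% t(A)) / ct1
    } else {
      btn <- matrix(0, n, K)
      for (r in seq_len(K)) btn[, r] <- rowSums(matrix(A[, t, r, ], n, K) * bb) / ct1
      bt <- btn
    }
  }
  g1 <- matrix(alph[, 1L, ], n, K) * bt
  g1 <- g1 / rowSums(g1)
  list(loglik = loglik, gamma1 = g1, xi_person = xi_person,
       xiw_person = xiw_person, xi_full = xi_full)
}

#' Forward-backward smoothing for one latent sequence
#'
#' Standard scaled filtering-smoothing over latent classes given class-
#' conditional log-densities per wave. A missing (unobserved) wave is encoded
#' as a row of zeros (unit emission term), so the chain marginalizes over it
#' and the wave contributes no information.
#'
#' @param pi0 initial class distribution, length K.
#' @param A K x K row-stochastic transition matrix.
#' @param log_dens T x K matrix of class-specific log-densities (rows of
#'   zeros for missing waves).
#' @param last_obs index of the last observed wave (default `nrow(log_dens)`);
#'   transitions beyond it are excluded from the pairwise posteriors.
#' @return List with `loglik`, `gamma` (T x K smoothed state marginals) and
#'   `xi` ((T-1) x K x K pairwise transition posteriors).
#' @export
forward_backward <- function(pi0, A, log_dens, last_obs = nrow(log_dens)) {
  log_dens <- as.matrix(log_dens)
  Tn <- nrow(log_dens); K <- ncol(log_dens)
  if (Tn < 1L) stop("empty sequence")
  if (Tn == 1L) {
    a <- log(pi0 + 1e-300) + log_dens[1L, ]
    ll <- logsumexp(a)
    return(list(loglik = ll, gamma = matrix(exp(a - ll), 1L, K),
                xi = array(0, c(0L, K, K))))
  }
  LB <- array(0, c(1L, Tn, K))
  LB[1L, , ] <- log_dens
  eng <- fb_engine(pi0, A, LB, lastT = last_obs, keep_xi = TRUE)
  ## smoothed marginals at every wave from the pairwise posteriors
  gamma <- matrix(0, Tn, K)
  gamma[1L, ] <- eng$gamma1[1L, ]
  xi <- array(eng$xi_full[1L, , , ], c(Tn - 1L, K, K))
  for (t in 2:Tn) {
    if (t <= last_obs) {
      gamma[t, ] <- colSums(matrix(xi[t - 1L, , ], K, K))
    } else {
      gamma[t, ] <- gamma[t - 1L, ] %*% A
    }
  }
  list(loglik = eng$loglik[1L], gamma = gamma, xi = xi)
}

## build the n_persons x T x K log-density array plus bookkeeping
build_ld_array <- function(data, meas) {
  LD <- class_log_densities(meas, data)
  K <- ncol(LD)
  ids <- unique(data$person_id)
  pidx <- match(data$person_id, ids)
  Tn <- max(data$wave) + 1L
  n <- length(ids)
  LB <- array(0, c(n, Tn, K))
  for (k in seq_len(K)) {
    LB[cbind(pidx, data$wave + 1L, k)] <- LD[, k]
  }
  lastT <- as.integer(tapply(data$wave, pidx, max) + 1L)
  list(LB = LB, lastT = lastT, n = n, Tn = Tn, K = K, ids = ids)
}

## map between probability scale and reference-logit parameterization
pi_to_theta <- function(pi0) log(pmax(pi0[-1L], 1e-12) / pmax(pi0[1L], 1e-12))
theta_to_pi <- function(s) softmax(c(0, s))
A_to_theta <- function(A) {
  K <- nrow(A)
  unlist(lapply(seq_len(K), function(r) {
    eta <- log(pmax(A[r, -r], 1e-12) / pmax(A[r, r], 1e-12))
    pmin(pmax(eta, -30), 30)
  }))
}
theta_to_A <- function(th, K) {
  A <- matrix(0, K, K)
  i <- 0L
  for (r in seq_len(K)) {
    eta <- rep(0, K)
    eta[-r] <- th[i + seq_len(K - 1L)]
    i <- i + K - 1L
    A[r, ] <- softmax(eta)
  }
  A
}

#' Fit a two-step latent Markov model
#'
#' EM estimation of the initial class distribution and the time-homogeneous
#' transition matrix, with the measurement model frozen at its step-1
#' estimates (its class-specific log-densities are the only data summary
#' used). Each respondent is a case; all observed waves contribute, a missing
#' wave is marginalized out and provides no information about the adjacent
#' transitions. Standard errors are cluster-robust sandwich estimates with
#' the respondent as the primary sampling unit; they ignore step-1 sampling
#' uncertainty (documented limitation of the plain two-step variance).
#'
#' @param data an [as_panel()] dataset.
#' @param measurement an [fit_lca()] result (or bare [measurement_model()]);
#'   never updated.
#' @param max_iter,tol EM control (relative log-likelihood change).
#' @param se compute cluster-robust standard errors.
#' @param init_pi0,init_A optional starting values.
#' @return Object of class `markov_fit` with `pi0`, `A`, `se_pi0`, `se_A`,
#'   `loglik`, `n_persons`, `n_transitions_informative`, `converged`.
#' @export
fit_latent_markov <- function(data, measurement, max_iter = 2000L,
                              tol = 1e-8, se = TRUE,
                              init_pi0 = NULL, init_A = NULL) {
  bd <- build_ld_array(data, measurement)
  if (bd$Tn < 2L) stop("latent Markov model needs at least two waves")
  K <- bd$K
  pi0 <- init_pi0 %||% rep(1 / K, K)
  A <- init_A %||% (diag(K) * 0.7 + 0.3 / K)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eng <- fb_engine(pi0, A, bd$LB, bd$lastT)
    ll <- sum(eng$loglik)
    pi0 <- colMeans(eng$gamma1)
    xi_tot <- apply(eng$xi_person, c(2L, 3L), sum)
    A <- xi_tot / pmax(rowSums(xi_tot), 1e-300)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
  }
  ## report the likelihood at the final parameter values
  ll <- sum(fb_engine(pi0, A, bd$LB, bd$lastT)$loglik)
  if (!converged) {
    warning("latent Markov EM did not converge in ", max_iter, " iterations")
  }
  fit <- structure(list(
    pi0 = pi0, A = A, loglik = ll, n_persons = bd$n,
    n_transitions_informative = sum(bd$lastT - 1L),
    converged = converged, n_iter = iter,
    measurement_source = if (inherits(measurement, "lca_fit"))
      measurement$measurement else measurement,
    se_pi0 = NULL, se_A = NULL
  ), class = "markov_fit")
  if (se) {
    ses <- markov_sandwich(pi0, A, bd)
    fit$se_pi0 <- ses$se_pi0
    fit$se_A <- ses$se_A
  }
  lbl <- class_labels(K)
  names(fit$pi0) <- lbl
  dimnames(fit$A) <- list(lbl, lbl)
  if (!is.null(fit$se_A)) dimnames(fit$se_A) <- dimnames(fit$A)
  fit
}

class_labels <- function(K) {
  if (K == 4L) c("healthy", "depressed-worried", "fear", "high-comorbidity")
  else paste0("class", seq_len(K))
}

## per-person score vectors via the Fisher identity, on the reference-logit scale
markov_scores <- function(theta, bd) {
  K <- bd$K
  pi0 <- theta_to_pi(theta[seq_len(K - 1L)])
  A <- theta_to_A(theta[-seq_len(K - 1L)], K)
  eng <- fb_engine(pi0, A, bd$LB, bd$lastT)
  n <- bd$n
  G <- matrix(0, n, length(theta))
  G[, seq_len(K - 1L)] <- eng$gamma1[, -1L, drop = FALSE] -
    matrix(pi0[-1L], n, K - 1L, byrow = TRUE)
  col <- K - 1L
  for (r in seq_len(K)) {
    xr <- matrix(eng$xi_person[, r, ], n, K)
    tot <- rowSums(xr)
    for (k in seq_len(K)) {
      if (k == r) next
      col <- col + 1L
      G[, col] <- xr[, k] - tot * A[r, k]
    }
  }
  G
}

markov_sandwich <- function(pi0, A, bd, h = 1e-5) {
  K <- bd$K
  theta <- c(pi_to_theta(pi0), A_to_theta(A))
  P <- length(theta)
  Sc <- markov_scores(theta, bd)
  meat <- crossprod(Sc)
  H <- matrix(0, P, P)
  for (p in seq_len(P)) {
    tp <- theta; tp[p] <- tp[p] + h
    tm <- theta; tm[p] <- tm[p] - h
    H[, p] <- (colSums(markov_scores(tp, bd)) -
               colSums(markov_scores(tm, bd))) / (2 * h)
  }
  info <- -(H + t(H)) / 2
  Vi <- tryCatch(solve(info), error = function(e) MASS_ginv(info))
  V <- Vi %*% meat %*% t(Vi)
  ## delta method back to probabilities
  Jp <- matrix(0, K, K - 1L)
  for (k in seq_len(K)) for (m in 2:K) {
    Jp[k, m - 1L] <- pi0[k] * ((k == m) - pi0[m])
  }
  Vs <- V[seq_len(K - 1L), seq_len(K - 1L), drop = FALSE]
  se_pi0 <- sqrt(pmax(diag(Jp %*% Vs %*% t(Jp)), 0))
  se_A <- matrix(0, K, K)
  off <- K - 1L
  for (r in seq_len(K)) {
    idx <- off + seq_len(K - 1L)
    off <- off + K - 1L
    Jr <- matrix(0, K, K - 1L)
    cols <- setdiff(seq_len(K), r)
    for (k in seq_len(K)) for (mi in seq_along(cols)) {
      m <- cols[mi]
      Jr[k, mi] <- A[r, k] * ((k == m) - A[r, m])
    }
    Vr <- V[idx, idx, drop = FALSE]
    se_A[r, ] <- sqrt(pmax(diag(Jr %*% Vr %*% t(Jr)), 0))
  }
  list(se_pi0 = se_pi0, se_A = se_A)
}

## minimal Moore-Penrose fallback for near-singular information
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1L]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.markov_fit <- function(x, ...) {
  cat(sprintf("Latent Markov fit: K = %d, %d persons, %d informative transitions\n",
              length(x$pi0), x$n_persons, x$n_transitions_informative))
  cat(sprintf("logLik = %.3f (%sconverged in %d iterations)\n", x$loglik,
              if (x$converged) "" else "NOT ", x$n_iter))
  cat("initial distribution:\n")
  print(round(x$pi0, 4))
  cat("transition matrix (per interval, percent):\n")
  print(transition_table(x))
  invisible(x)
}

#' Transition probabilities as a percentage table
#'
#' @param fit a [fit_latent_markov()] result.
#' @param digits rounding for display.
#' @return K x K matrix of percentages (rows = origin class, in prevalence
#'   order), rows summing to 100 up to rounding.
#' @export
transition_table <- function(fit, digits = 1L) {
  round(100 * fit$A, digits)
}
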