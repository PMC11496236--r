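# calibrated synthetic cohort generator

#' Default class prevalences
#'
#' Four-class mixing proportions calibrated to the published population
#' estimates (healthy 94.1%, depressed-worried 3.6%, fear 1.8%, high
#' comorbidity 0.6%), normalized to sum exactly to one.
#'
#' @return Named probability vector of length 4.
#' @export
default_prevalences <- function() {
  p <- c(healthy = 94.1, `depressed-worried` = 3.6, fear = 1.8,
         `high-comorbidity` = 0.6)
  p / sum(p)
}

#' Default latent transition matrix
#'
#' Time-homogeneous 4x4 transition matrix per ~3-year inter-wave interval,
#' calibrated to the published estimates: the healthy class is highly stable
#' (97.6% stay, 1.9% to depressed-worried), the depressed-worried class most
#' often recovers (39.7% to healthy, 36.5% stay), the fear class is the most
#' persistent unhealthy class (67.3% stay), and the high-comorbidity class
#' most often moves to the fear class (43.5%). Cells not individually
#' published are filled by the row complement; rows are normalized to sum to
#' one.
#'
#' @return Row-stochastic 4x4 matrix.
#' @export
default_transitions <- function() {
  A <- rbind(
    c(97.6, 1.9, 0.4, 0.1),
    c(39.7, 36.5, 18.2, 5.6),
    c(12.5, 14.7, 67.3, 5.6),
    c(7.0, 11.1, 43.5, 38.4)
  )
  A <- A / rowSums(A)
  dimnames(A) <- list(names(default_prevalences()),
                      names(default_prevalences()))
  A
}

#' Default emission (indicator) probabilities
#'
#' Per-class 12-month disorder probabilities at follow-up waves. The published
#' class-specific estimates are not public, so these are stand-in values that
#' reproduce the qualitative class profiles: a healthy class with uniformly
#' rare disorders, a depressed-worried class dominated by major depression and
#' GAD, a fear class dominated by phobic and panic disorders, and a
#' high-comorbidity class elevated on (almost) everything.
#'
#' @return 4x8 matrix of probabilities, rows = classes, columns =
#'   [lc_indicators()].
#' @export
default_emissions <- function() {
  E <- rbind(
    c(0.015, 0.005, 0.005, 0.005, 0.005, 0.010, 0.020, 0.005),
    c(0.750, 0.300, 0.150, 0.100, 0.050, 0.120, 0.150, 0.350),
    c(0.120, 0.050, 0.030, 0.350, 0.300, 0.550, 0.650, 0.100),
    c(0.700, 0.500, 0.300, 0.550, 0.500, 0.600, 0.650, 0.550)
  )
  dimnames(E) <- list(names(default_prevalences()), lc_indicators())
  E
}

#' Default per-wave retention probabilities
#'
#' Exact ratios of the observed wave sizes 6646/5303/4618/4007, so that the
#' expected total record count for a cohort of 6646 persons is exactly
#' 20574 and quota-based dropout reproduces the wave sizes deterministically.
#'
#' @return Numeric vector of length 3 (retention into waves 1, 2, 3).
#' @export
default_retention <- function() {
  c(5303 / 6646, 4618 / 5303, 4007 / 4618)
}

#' Generator configuration
#'
#' Bundles every true parameter of the synthetic cohort: class prevalences,
#' transition dynamics, emission probabilities, a baseline measurement effect
#' (logit offset at wave 0), monotone attrition, and optional class-linked
#' covariates. Defaults reproduce the published study conditions: 6646
#' persons over 4 waves with attrition to 5303/4618/4007 and the published
#' prevalences and transition probabilities.
#'
#' @param n_individuals cohort size at wave 0.
#' @param n_waves number of waves (>= 2 for panel simulation).
#' @param pi0 initial class distribution (length K, sums to 1).
#' @param A K x K row-stochastic transition matrix per interval.
#' @param emissions K x J matrix of indicator probabilities at follow-up.
#' @param baseline_delta length-J vector of logit offsets (>= 0) added to
#'   every indicator at wave 0, emulating the more sensitive baseline
#'   assessment.
#' @param retention per-wave retention probabilities in (0, 1], length
#'   `n_waves - 1`; dropout is monotone.
#' @param dropout `"quota"` retains exactly `round(retention * n_at_risk)`
#'   randomly chosen persons per wave; `"bernoulli"` drops persons
#'   independently; `"none"` ignores `retention`.
#' @param covariate_spec optional list of covariate specifications; see
#'   [covariate_spec()].
#' @param seed integer seed; all simulation randomness derives from it.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_individuals = 6646L,
                             n_waves = 4L,
                             pi0 = default_prevalences(),
                             A = default_transitions(),
                             emissions = default_emissions(),
                             baseline_delta = rep(0.5, ncol(emissions)),
                             retention = default_retention(),
                             dropout = c("quota", "bernoulli", "none"),
                             covariate_spec = NULL,
                             seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_waves = as.integer(n_waves),
              pi0 = pi0, A = A, emissions = as.matrix(emissions),
              baseline_delta = baseline_delta,
              retention = retention, dropout = match.arg(dropout),
              covariate_spec = covariate_spec, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  K <- length(cfg$pi0)
  if (!is_prob_vector(cfg$pi0)) stop("invalid generator field 'pi0': must be a probability vector summing to 1")
  if (!is_stochastic_matrix(cfg$A) || nrow(cfg$A) != K || ncol(cfg$A) != K)
    stop("invalid generator field 'A': must be a ", K, "x", K, " row-stochastic matrix")
  if (!is.matrix(cfg$emissions) || nrow(cfg$emissions) != K ||
      any(cfg$emissions < 0) || any(cfg$emissions > 1))
    stop("invalid generator field 'emissions': K x J matrix with entries in [0,1]")
  J <- ncol(cfg$emissions)
  if (length(cfg$baseline_delta) != J || any(cfg$baseline_delta < 0))
    stop("invalid generator field 'baseline_delta': length-J vector of offsets >= 0")
  if (cfg$n_waves < 2L) stop("invalid generator field 'n_waves': must be >= 2")
  if (cfg$dropout != "none") {
    if (length(cfg$retention) != cfg$n_waves - 1L ||
        any(cfg$retention <= 0) || any(cfg$retention > 1))
      stop("invalid generator field 'retention': length n_waves-1, entries in (0,1]")
  }
  if (cfg$n_individuals < 1L) stop("invalid generator field 'n_individuals': must be >= 1")
  invisible(cfg)
}

#' Specify a class-linked covariate for simulation
#'
#' @param name column name.
#' @param type `"binary"` (class-conditional Bernoulli) or `"normal"`
#'   (class-conditional mean, shared sd).
#' @param prob per-class success probability (binary type), length K.
#' @param mean per-class mean (normal type), length K.
#' @param sd shared standard deviation (normal type).
#' @param time_varying if `FALSE` (e.g. sex, childhood abuse) the wave-0 value
#'   is carried forward.
#' @param trans_coef optional K x K matrix of multinomial-logit coefficients:
#'   `trans_coef[r, k]` is added to the logit of moving from class `r` to
#'   class `k` (relative to staying, diagonal ignored) per unit of the
#'   covariate measured at the origin wave.
#' @param missing_rate probability a recorded value is set missing (MCAR).
#' @return Object of class `lc_covariate_spec`.
#' @export
covariate_spec <- function(name, type = c("binary", "normal"), prob = NULL,
                           mean = NULL, sd = 1, time_varying = TRUE,
                           trans_coef = NULL, missing_rate = 0) {
  type <- match.arg(type)
  if (type == "binary" && is.null(prob)) stop("binary covariate needs 'prob'")
  if (type == "normal" && is.null(mean)) stop("normal covariate needs 'mean'")
  structure(list(name = name, type = type, prob = prob, mean = mean, sd = sd,
                 time_varying = time_varying, trans_coef = trans_coef,
                 missing_rate = missing_rate),
            class = "lc_covariate_spec")
}

draw_covariate <- function(spec, classes) {
  K <- max(classes)
  switch(spec$type,
    binary = stats::rbinom(length(classes), 1L, spec$prob[classes]),
    normal = stats::rnorm(length(classes), spec$mean[classes], spec$sd),
    stop("unknown covariate distribution type: ", spec$type)
  )
}

## survivors among persons at risk, per the configured dropout mode
apply_retention <- function(at_risk, retention, mode) {
  n <- length(at_risk)
  if (mode == "none" || n == 0L) return(at_risk)
  if (mode == "quota") {
    keep <- round(n * retention)
    at_risk[sort(sample.int(n, min(keep, n)))]
  } else {
    at_risk[stats::runif(n) < retention]
  }
}

#' Simulate a longitudinal cohort
#'
#' Samples a latent class path per person (initial distribution `pi0`, then
#' the transition matrix row by row), binary indicators conditionally
#' independent given class with the baseline logit offset applied at wave 0,
#' monotone dropout after wave 0, and optional class-linked covariates. When a
#' covariate specification carries transition coefficients, the covariate
#' value at wave T enters the multinomial logit of the transition T -> T+1
#' (staying is the reference), so covariate effects on course can be injected
#' and recovered.
#'
#' @param config a [generator_config()].
#' @return An [as_panel()] dataset including `latent_class_truth`.
#' @export
simulate_panel <- function(config) {
  validate_generator_config(config)
  cfg <- config
  K <- length(cfg$pi0); J <- ncol(cfg$emissions); Tn <- cfg$n_waves
  n <- cfg$n_individuals
  with_seed(cfg$seed, {
    ## latent paths + covariates wave by wave (covariates may feed transitions)
    z <- matrix(NA_integer_, n, Tn)
    z[, 1L] <- sample.int(K, n, replace = TRUE, prob = cfg$pi0)
    alive <- vector("list", Tn)
    alive[[1L]] <- seq_len(n)
    covs <- list()  # name -> n x Tn matrix
    for (sp in cfg$covariate_spec %||% list()) covs[[sp$name]] <- matrix(NA_real_, n, Tn)

    base_logits <- log(cfg$A / diag(cfg$A)[row(cfg$A)])  # stay as reference
    for (t in seq_len(Tn)) {
      idx <- alive[[t]]
      for (sp in cfg$covariate_spec %||% list()) {
        if (t == 1L || sp$time_varying) {
          covs[[sp$name]][idx, t] <- draw_covariate(sp, z[idx, t])
        } else {
          covs[[sp$name]][idx, t] <- covs[[sp$name]][idx, 1L]
        }
      }
      if (t == Tn) break
      surv <- apply_retention(idx, cfg$retention[t], cfg$dropout)
      alive[[t + 1L]] <- surv
      if (length(surv)) {
        eta <- base_logits[z[surv, t], , drop = FALSE]  # m x K
        for (sp in cfg$covariate_spec %||% list()) {
          if (!is.null(sp$trans_coef)) {
            x <- covs[[sp$name]][surv, t]
            eta <- eta + x * sp$trans_coef[z[surv, t], , drop = FALSE]
          }
        }
        P <- softmax_rows(eta)
        cum <- t(apply(P, 1L, cumsum))
        cum[, K] <- 1  # guard against rounding at the top
        u <- stats::runif(length(surv))
        z[surv, t + 1L] <- max.col(u < cum, "first")
      }
    }

    ## flatten to long format and sample indicators
    recs <- do.call(rbind, lapply(seq_len(Tn), function(t) {
      idx <- alive[[t]]
      if (!length(idx)) return(NULL)
      data.frame(person_id = idx, wave = t - 1L, latent_class_truth = z[idx, t])
    }))
    recs <- recs[order(recs$person_id, recs$wave), , drop = FALSE]
    ## exact emission probabilities; the baseline logit shift (which needs
    ## clipping away from 0/1) is applied only where delta is nonzero
    P <- cfg$emissions[recs$latent_class_truth, , drop = FALSE]
    b0 <- recs$wave == 0L
    for (j in which(cfg$baseline_delta != 0)) {
      P[b0, j] <- expit(logit(clip01(P[b0, j])) + cfg$baseline_delta[j])
    }
    Y <- matrix(stats::rbinom(length(P), 1L, P), nrow(recs), J)
    colnames(Y) <- colnames(cfg$emissions) %||% paste0("y", seq_len(J))
    out <- cbind(recs[c("person_id", "wave")], as.data.frame(Y))
    for (sp in cfg$covariate_spec %||% list()) {
      v <- covs[[sp$name]][cbind(out$person_id, out$wave + 1L)]
      if (sp$missing_rate > 0) {
        v[stats::runif(length(v)) < sp$missing_rate] <- NA
      }
      out[[sp$name]] <- v
    }
    out$latent_class_truth <- recs$latent_class_truth
    rownames(out) <- NULL
    as_panel(out, indicators = colnames(Y))
  })
}

#' Simulate independent pooled records
#'
#' iid single-record mode matching the pooled measurement step, in which each
#' wave is a case: classes are drawn from `pi0` with no Markov structure and
#' indicators from the class-specific emission probabilities. The baseline
#' flag (and hence the baseline logit offset) is set globally.
#'
#' @param config a [generator_config()].
#' @param n_records number of records.
#' @param is_baseline logical; mark all records as baseline measurements.
#' @return An [as_panel()] dataset with one wave per pseudo-person.
#' @export
simulate_pooled <- function(config, n_records, is_baseline = FALSE) {
  validate_generator_config(config)
  if (n_records < 1L) stop("n_records must be >= 1")
  cfg <- config
  K <- length(cfg$pi0); J <- ncol(cfg$emissions)
  with_seed(cfg$seed, {
    z <- sample.int(K, n_records, replace = TRUE, prob = cfg$pi0)
    P <- cfg$emissions[z, , drop = FALSE]
    if (is_baseline) {
      for (j in which(cfg$baseline_delta != 0)) {
        P[, j] <- expit(logit(clip01(P[, j])) + cfg$baseline_delta[j])
      }
    }
    Y <- matrix(stats::rbinom(length(P), 1L, P), n_records, J)
    colnames(Y) <- colnames(cfg$emissions) %||% paste0("y", seq_len(J))
    out <- data.frame(person_id = seq_len(n_records),
                      wave = if (is_baseline) 0L else 1L)
    out <- cbind(out, as.data.frame(Y))
    out$latent_class_truth <- z
    as_panel(out, indicators = colnames(Y))
  })
}

#' Attach class-conditional covariates to an existing simulated dataset
#'
#' Post-hoc covariate generation from class-conditional distributions (no
#' feedback into transitions); requires the simulation truth column.
#'
#' @param data an [as_panel()] dataset with `latent_class_truth`.
#' @param config a [generator_config()] with a non-empty `covariate_spec`.
#' @param seed optional seed (defaults to a substream of `config$seed`).
#' @return The dataset with covariate columns added.
#' @export
attach_covariates <- function(data, config, seed = NULL) {
  if (is.null(config$covariate_spec) || !length(config$covariate_spec)) {
    stop("config$covariate_spec is empty")
  }
  if (is.null(data$latent_class_truth)) {
    stop("attach_covariates needs the latent_class_truth column")
  }
  seed <- seed %||% derive_seed(config$seed, "covariates")
  ind <- panel_indicators(data)
  with_seed(seed, {
    ord <- order(data$person_id, data$wave)
    for (sp in config$covariate_spec) {
      v <- rep(NA_real_, nrow(data))
      if (sp$time_varying) {
        v <- draw_covariate(sp, data$latent_class_truth)
      } else {
        first <- !duplicated(data$person_id[ord])
        v0 <- draw_covariate(sp, data$latent_class_truth[ord][first])
        v[ord] <- v0[cumsum(first)]
      }
      if (sp$missing_rate > 0) v[stats::runif(length(v)) < sp$missing_rate] <- NA
      data[[sp$name]] <- v
    }
    as_panel(as.data.frame(data), indicators = ind)
  })
}

#' Expected total record count under the configured attrition
#'
#' `E[records] = n * (1 + sum_t prod_{s<=t} retention_s)`; with the default
#' configuration this is exactly 6646 + 5303 + 4618 + 4007 = 20574.
#'
#' @param config a [generator_config()].
#' @return Expected number of person-wave records.
#' @export
expected_records <- function(config) {
  if (config$dropout == "none") return(config$n_individuals * config$n_waves)
  config$n_individuals * (1 + sum(cumprod(config$retention)))
}
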