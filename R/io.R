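# readers, writers, configuration and the end-to-end pipeline

#' Read a long-format panel CSV
#'
#' Expects one row per person-wave with columns `person_id`, `wave`, the
#' indicator columns (canonical names `mdd,dys,bip,pan,ago,soc,spe,gad`
#' unless `indicators` is given) and optional covariate columns. Empty
#' fields are parsed as missing covariate values. Non-binary indicator cells
#' are a hard error citing the offending rows; monotone-dropout violations
#' are reported as a warning with counts.
#'
#' @param path CSV file path.
#' @param indicators optional indicator column names.
#' @return An [as_panel()] dataset.
#' @export
read_panel <- function(path, indicators = NULL) {
  df <- utils::read.csv(path, na.strings = c("", "NA"),
                        stringsAsFactors = FALSE)
  for (col in c("person_id", "wave")) {
    if (!col %in% names(df)) stop("missing required column: ", col)
  }
  data <- as_panel(df, indicators = indicators)
  bad <- check_monotone(data)
  if (length(bad)) {
    warning(length(bad), " person(s) violate monotone dropout (observed at ",
            "a wave without all earlier waves), e.g. person_id ", bad[1L])
  }
  covs <- setdiff(names(data), c("person_id", "wave", panel_indicators(data),
                                 "latent_class_truth"))
  n_miss <- vapply(covs, function(v) sum(is.na(data[[v]])), integer(1))
  attr(data, "missingness") <- n_miss
  data
}

#' Write a panel dataset to CSV
#'
#' Long format: `person_id`, `wave`, one column per indicator, covariate
#' columns, and (if present) the clearly suffixed simulation truth column.
#' Missing covariates are written as empty fields.
#'
#' @param data an [as_panel()] dataset.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(data, path) {
  ind <- panel_indicators(data)
  covs <- setdiff(names(data), c("person_id", "wave", ind, "latent_class_truth"))
  cols <- c("person_id", "wave", ind, covs,
            intersect("latent_class_truth", names(data)))
  utils::write.csv(as.data.frame(data)[cols], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Serialize / restore a generator configuration
#'
#' Flat-keyed YAML with matrices as nested lists, so configurations are
#' human-editable and diffable.
#'
#' @param config a [generator_config()].
#' @param path file path.
#' @return `write_generator_config` returns `path` invisibly;
#'   `read_generator_config` returns the restored `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  obj <- unclass(config)
  obj$A <- apply(config$A, 1L, as.numeric, simplify = FALSE)
  obj$emissions <- apply(config$emissions, 1L, as.numeric, simplify = FALSE)
  obj$pi0 <- as.numeric(config$pi0)
  obj$covariate_spec <- lapply(config$covariate_spec %||% list(), function(sp) {
    sp <- unclass(sp)
    if (!is.null(sp$trans_coef)) {
      sp$trans_coef <- apply(sp$trans_coef, 1L, as.numeric, simplify = FALSE)
    }
    sp
  })
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  obj <- yaml::read_yaml(path)
  A <- do.call(rbind, obj$A)
  E <- do.call(rbind, obj$emissions)
  colnames(E) <- lc_indicators()[seq_len(ncol(E))]
  cspec <- lapply(obj$covariate_spec %||% list(), function(sp) {
    covariate_spec(name = sp$name, type = sp$type,
                   prob = unlist(sp$prob), mean = unlist(sp$mean),
                   sd = sp$sd %||% 1,
                   time_varying = isTRUE(sp$time_varying),
                   trans_coef = if (!is.null(sp$trans_coef))
                     do.call(rbind, sp$trans_coef),
                   missing_rate = sp$missing_rate %||% 0)
  })
  if (!length(cspec)) cspec <- NULL
  generator_config(n_individuals = obj$n_individuals, n_waves = obj$n_waves,
                   pi0 = unlist(obj$pi0), A = A, emissions = E,
                   baseline_delta = unlist(obj$baseline_delta),
                   retention = unlist(obj$retention), dropout = obj$dropout,
                   covariate_spec = cspec, seed = obj$seed)
}

log_stage <- function(stage, ..., file = NULL) {
  kv <- list(...)
  msg <- paste0("[", stage, "] ",
                paste(names(kv), unlist(kv), sep = "=", collapse = " "))
  message(msg)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE)
}

#' Run the full two-step analysis pipeline
#'
#' Orchestrates: optional simulation from a generator configuration,
#' measurement-model selection over a K range, the two-step latent Markov
#' model at the chosen (or forced) K, and per-covariate analyses (class
#' profiles and transition prediction). Every stage derives its seed from
#' the master seed through a named substream, so two runs with the same
#' configuration produce identical bundles. A stage failure halts with the
#' stage name; outputs produced so far are kept in the returned condition.
#'
#' @param data an [as_panel()] dataset, or `NULL` to simulate from
#'   `generator`.
#' @param generator a [generator_config()] (used when `data` is `NULL`).
#' @param k_range integer range of class counts to explore.
#' @param K forced class count for the structural step (default: chosen by
#'   the selection report).
#' @param covariates character vector of covariate columns to analyse.
#' @param fixed_covariates covariates treated as time-fixed (wave-0 value
#'   carried forward).
#' @param n_starts,start_iters multi-start budget for the measurement fits.
#' @param gof_B,lrt_B bootstrap replicates in the selection stage (0 skips).
#' @param seed master seed.
#' @param out_dir optional directory; fitted objects and reports are written
#'   there as CSV/JSON.
#' @param verbose print structured progress lines.
#' @return List with `data`, `selection`, `lca_fit`, `markov_fit`,
#'   `profiles`, `transition_effects`, `seed`.
#' @export
run_pipeline <- function(data = NULL, generator = NULL,
                         k_range = 1:5, K = NULL,
                         covariates = character(0),
                         fixed_covariates = character(0),
                         n_starts = 16L, start_iters = 100L,
                         gof_B = 0L, lrt_B = 0L, seed = 1L,
                         out_dir = NULL, verbose = TRUE) {
  logf <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    logf <- file.path(out_dir, "pipeline.log")
  }
  say <- function(stage, ...) if (verbose) log_stage(stage, ..., file = logf)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(data)) {
    if (is.null(generator)) stop("either data or generator must be supplied")
    generator$seed <- derive_seed(seed, "generator")
    t0 <- proc.time()[3]
    data <- run_stage("simulate", simulate_panel(generator))
    say("simulate", n = nrow(data), persons = generator$n_individuals,
        seed = generator$seed, secs = round(proc.time()[3] - t0, 2))
    if (!is.null(out_dir)) write_panel(data, file.path(out_dir, "panel.csv"))
  }

  t0 <- proc.time()[3]
  sel <- run_stage("select-k", select_k(data, min(k_range), max(k_range),
                                        n_starts = n_starts,
                                        start_iters = start_iters,
                                        gof_B = gof_B, lrt_B = lrt_B,
                                        seed = derive_seed(seed, "starts")))
  say("select-k", chosen_K = attr(sel, "chosen_K"),
      secs = round(proc.time()[3] - t0, 2))
  if (!is.null(out_dir)) {
    utils::write.csv(as.data.frame(sel), file.path(out_dir, "selection.csv"),
                     row.names = FALSE)
  }
  K <- K %||% attr(sel, "chosen_K")
  fit <- attr(sel, "fits")[[match(K, as.data.frame(sel)$K)]]
  say("fit-lca", K = K, loglik = round(fit$loglik, 2),
      converged = fit$converged)
  if (!is.null(out_dir)) write_lca_fit(fit, file.path(out_dir, "lca_fit.json"))

  t0 <- proc.time()[3]
  mk <- run_stage("fit-markov", fit_latent_markov(data, fit))
  say("fit-markov", loglik = round(mk$loglik, 2), converged = mk$converged,
      secs = round(proc.time()[3] - t0, 2))
  if (!is.null(out_dir)) {
    utils::write.csv(as.data.frame(transition_table(mk)),
                     file.path(out_dir, "transitions.csv"))
  }

  profiles <- NULL
  effects <- list()
  if (length(covariates)) {
    profiles <- run_stage("profile-covariates",
                          profile_classes(fit, data, covariates))
    say("profile-covariates", n = length(covariates))
    for (v in covariates) {
      effects[[v]] <- run_stage(paste0("predict-transitions:", v),
        transition_logit(fit, data, v,
                         time_varying = !(v %in% fixed_covariates)))
      say("predict-transitions", covariate = v,
          converged = effects[[v]]$converged)
    }
    if (!is.null(out_dir)) {
      utils::write.csv(profiles$profiles,
                       file.path(out_dir, "profiles.csv"), row.names = FALSE)
      utils::write.csv(do.call(rbind, lapply(effects, `[[`, "table")),
                       file.path(out_dir, "transition_effects.csv"),
                       row.names = FALSE)
    }
  }
  list(data = data, selection = sel, lca_fit = fit, markov_fit = mk,
       profiles = profiles, transition_effects = effects, seed = seed)
}
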