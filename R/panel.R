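# the long-format panel container shared by all stages

#' Canonical disorder indicator names
#'
#' Column names used by default for the eight 12-month mood and anxiety
#' disorder indicators: major depressive disorder, dysthymia, bipolar
#' disorder, panic disorder, agoraphobia, social phobia, specific phobia and
#' generalized anxiety disorder.
#'
#' @return Character vector of length 8.
#' @export
lc_indicators <- function() {
  c("mdd", "dys", "bip", "pan", "ago", "soc", "spe", "gad")
}

#' Construct and validate a long-format panel dataset
#'
#' One row per person-wave ("each wave is a case" in the pooled measurement
#' step). Indicator columns must be strictly binary; `(person_id, wave)` pairs
#' must be unique. Waves are 0-based; wave 0 is the baseline assessment, which
#' may carry a measurement effect on the indicators.
#'
#' @param df data frame with columns `person_id`, `wave`, the indicator
#'   columns, and optionally covariates and a `latent_class_truth` column
#'   (simulation only).
#' @param indicators character vector of indicator column names; defaults to
#'   the intersection of [lc_indicators()] with `names(df)`.
#' @return `df` with class `lc_panel` and an `indicators` attribute.
#' @export
as_panel <- function(df, indicators = NULL) {
  stopifnot(is.data.frame(df))
  if (!all(c("person_id", "wave") %in% names(df))) {
    stop("panel data must have columns 'person_id' and 'wave'")
  }
  if (is.null(indicators)) {
    indicators <- intersect(lc_indicators(), names(df))
    if (length(indicators) == 0L) {
      stop("no indicator columns found; pass `indicators` explicitly")
    }
  }
  missing_cols <- setdiff(indicators, names(df))
  if (length(missing_cols)) {
    stop("missing indicator column(s): ", paste(missing_cols, collapse = ", "))
  }
  Y <- as.matrix(df[indicators])
  if (anyNA(Y)) {
    bad <- which(rowSums(is.na(Y)) > 0)
    stop("missing values in indicator columns at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (!all(Y %in% c(0, 1))) {
    bad <- which(rowSums(!(Y == 0 | Y == 1)) > 0)
    stop("non-binary indicator values at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  key <- paste(df$person_id, df$wave)
  if (anyDuplicated(key)) {
    stop("duplicated (person_id, wave) pairs, e.g. row ",
         which(duplicated(key))[1L])
  }
  structure(df, class = unique(c("lc_panel", class(df))),
            indicators = indicators)
}

panel_indicators <- function(data) {
  ind <- attr(data, "indicators")
  if (is.null(ind)) ind <- intersect(lc_indicators(), names(data))
  if (length(ind) == 0L) stop("cannot determine indicator columns")
  ind
}

panel_matrix <- function(data) {
  as.matrix(as.data.frame(data)[panel_indicators(data)])
}

#' @export
print.lc_panel <- function(x, ...) {
  ind <- panel_indicators(x)
  cat(sprintf("<lc_panel> %d records, %d persons, waves %s, %d indicators\n",
              nrow(x), length(unique(x$person_id)),
              paste(range(x$wave), collapse = "-"), length(ind)))
  cat("indicators:", paste(ind, collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more records\n")
  invisible(x)
}

## rows violating monotone dropout: person observed at wave t but not t-1
check_monotone <- function(data) {
  sp <- split(data$wave, data$person_id)
  bad <- vapply(sp, function(w) !all(sort(w) == seq_len(length(w)) - 1L),
                logical(1))
  names(sp)[bad]
}
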