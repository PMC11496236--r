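# internal numerical and RNG helpers

clip01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

## row-wise softmax of a matrix of logits
softmax_rows <- function(eta) {
  m <- apply(eta, 1L, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

softmax <- function(eta) {
  e <- exp(eta - max(eta))
  e / sum(e)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Derive a named substream seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams (generator, starts, bootstrap, ...), so that independent stages
#' of a pipeline use decorrelated but reproducible random number streams.
#'
#' @param master integer master seed.
#' @param stream character substream name.
#' @param index optional integer (e.g. replicate number) folded into the seed.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "generator")
#' derive_seed(1, "bootstrap", index = 7)
derive_seed <- function(master, stream, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  s <- (abs(master) %% 2147483647) * 31 + h * 7919 + index * 104729
  as.integer(s %% 2147483646L + 1L)
}

## evaluate code under a seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

is_prob_vector <- function(x, tol = 1e-8) {
  is.numeric(x) && all(x >= 0) && abs(sum(x) - 1) < tol
}

is_stochastic_matrix <- function(A, tol = 1e-8) {
  is.matrix(A) && all(A >= 0) && all(abs(rowSums(A) - 1) < tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
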