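#' @keywords internal
"_PACKAGE"

# Deterministic substream derivation: one master seed drives every stage
# (covariates, connectomes, codecs, splits, weight init) without the stages
# sharing or advancing a common RNG stream.

#' Derive a stage seed from a master seed
#'
#' Hashes a master seed together with a short stage tag into a 31-bit
#' integer, so that independent pipeline stages (cohort generation, per-member
#' codecs, splits, weight initialisation) each get a reproducible RNG stream
#' that does not collide with, or advance, any other stage's stream.
#'
#' @param seed integer master seed.
#' @param tag character stage label, e.g. `"codec"`, `"split"`.
#' @param k optional integer index (e.g. member number), default 0.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, tag, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647  # 2^31 - 1, prime
  h <- (as.double(seed) %% m)
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + (as.double(k) %% m)) %% m
  as.integer(h %% (m - 1)) + 1L
}

# run expr with a local RNG state seeded by `seed`; restores global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == floor(x)
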