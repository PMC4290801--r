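# Internal helpers shared across modules.

# Canonical (C-locale) sorting so that run reproducibility does not depend on
# the session collation.
csort <- function(x) sort(x, method = "radix")

corder <- function(...) order(..., method = "radix")

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# Derive k substream seeds (< 2^31) from one master seed.  Used wherever a run
# needs independent reproducible random streams (e.g. candidate selection vs
# Laplace noise) so that one stream can be replayed without the other.
derive_seeds <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, k)
}

# Clamp a frequency strictly inside (0, 1); `n` is the number of diploid
# individuals behind the estimate, giving bounds 1/(2n+1) and 1 - 1/(2n+1).
clamp_freq <- function(p, n) {
  lo <- 1 / (2 * n + 1)
  pmin(pmax(p, lo), 1 - lo)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == as.integer(x)
}
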