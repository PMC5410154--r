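#' Derive a per-stream seed from a global seed
#'
#' Every stochastic generator in the package draws its randomness from a
#' stream-specific seed derived from one global seed. The derivation is a
#' fixed affine hash of the stream label, so adding a new generator call to a
#' script never perturbs the random stream of an earlier one.
#'
#' @param seed Integer global seed.
#' @param stream Character label naming the consumer (e.g. "expression").
#' @return An integer seed in [0, 2^31 - 2].
#' @export
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Run code under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Reverse complement of DNA sequences
#'
#' Plain character in, plain character out; base-R implementation cheap
#' enough to sit in the assembler's inner loop.
#'
#' @param x Character vector of sequences over A, C, G, T, N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s)
    intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", s)))),
    "", USE.NAMES = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
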