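#' Derive a reproducible sub-stream seed
#'
#' All generators in the package draw from streams derived from one global
#' integer seed by stable string hashing of a purpose label, so that adding a
#' new generator never perturbs the streams of existing ones.
#'
#' @param seed Integer global seed.
#' @param purpose Character label naming the stream.
#' @return An integer in `[0, 2^31 - 2]` suitable for `set.seed()`.
#' @export
derive_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(purpose))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(purpose)) h <- (h * 31 + ch) %% m
  as.integer((abs(seed) * 7919 + h) %% m)
}

#' The 20 standard amino-acid one-letter codes
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Alignment and scoring parameters
#'
#' Parameters for global protein alignment and for placing raw alignment
#' scores on the bit scale via the Karlin-Altschul transform
#' `bits = (lambda * S - ln K) / ln 2`. Defaults are the standard gapped
#' BLOSUM62 constants.
#'
#' @param matrix Substitution matrix name understood by
#'   [Biostrings::pairwiseAlignment()].
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @param lambda,K Karlin-Altschul constants.
#' @return A list of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_opening = 11,
                         gap_extension = 1, lambda = 0.267, K = 0.041) {
  structure(list(matrix = matrix, gap_opening = gap_opening,
                 gap_extension = gap_extension, lambda = lambda, K = K),
            class = "align_params")
}

# round half up to integer percent (9/13 -> 69)
percent_round <- function(x) floor(100 * x + 0.5)
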