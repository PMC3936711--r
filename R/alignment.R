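#' Globally align two protein sequences and score the pair
#'
#' Needleman-Wunsch global alignment with affine gaps under a standard
#' substitution matrix (BLOSUM62 by default). The raw score is converted to
#' bits with the Karlin-Altschul transform `(lambda * S - ln K) / ln 2`, and
#' identity is the number of identical aligned positions divided by the
#' length of the shorter sequence (the CD-HIT convention).
#'
#' @param a,b Amino-acid sequences (character scalars).
#' @param params An [align_params()] object.
#' @return List with `raw_score`, `bit_score`, `identity`, `n_identical`, and
#'   the two gapped aligned strings `aligned_a`, `aligned_b`.
#' @export
align_pair <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = params$matrix,
    gapOpening = params$gap_opening, gapExtension = params$gap_extension)
  raw <- Biostrings::score(aln)
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  nid <- sum(ca == cb & ca != "-")
  list(raw_score = raw,
       bit_score = (params$lambda * raw - log(params$K)) / log(2),
       identity = nid / min(nchar(a), nchar(b)),
       n_identical = nid,
       aligned_a = pa, aligned_b = pb)
}

#' Karlin-Altschul E-value for a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` under the same constants used for bit
#' scores, with `m`, `n` the two sequence lengths.
#'
#' @param raw_score Raw alignment score.
#' @param m,n Sequence lengths.
#' @param params An [align_params()] object.
#' @return The expected number of chance hits (a non-negative number).
#' @export
alignment_evalue <- function(raw_score, m, n, params = align_params()) {
  params$K * m * n * exp(-params$lambda * raw_score)
}

#' Pairwise identity of two sequences
#'
#' Convenience wrapper returning only the identity fraction of [align_pair()].
#' @inheritParams align_pair
#' @return Identity in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, params = align_params()) {
  align_pair(a, b, params)$identity
}
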