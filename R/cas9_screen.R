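#' Map reference residue positions onto a candidate protein
#'
#' Globally aligns the candidate to the reference and reports, for each
#' queried 1-based reference position, the corresponding 1-based candidate
#' position, or `NA` when the reference column is a gap in the candidate
#' (the candidate lacks that region).
#'
#' @param candidate,reference Amino-acid sequences.
#' @param positions Integer vector of reference positions.
#' @param params An [align_params()] object.
#' @return Integer vector (named by position), `NA` for unaligned sites.
#' @export
map_positions <- function(candidate, reference, positions,
                          params = align_params()) {
  if (max(positions) > nchar(reference)) {
    stop("reference shorter than queried position ", max(positions))
  }
  a <- align_pair(candidate, reference, params)
  ca <- strsplit(a$aligned_a, "")[[1]]
  cr <- strsplit(a$aligned_b, "")[[1]]
  ref_pos <- cumsum(cr != "-")
  cand_pos <- cumsum(ca != "-")
  out <- setNames(rep(NA_integer_, length(positions)), positions)
  for (k in seq_along(positions)) {
    col <- which(cr != "-" & ref_pos == positions[k])
    if (length(col) == 1 && ca[col] != "-") out[k] <- cand_pos[col]
  }
  out
}

#' Screen a candidate Cas9 for the two catalytic residues
#'
#' Cas9 cleaves each target-DNA strand with a separate nuclease domain; the
#' canonical catalytic residues are D at reference position 10 (RuvC, cuts
#' the strand non-complementary to the crRNA) and H at position 840 (HNH,
#' cuts the complementary strand). Mutating either to A abolishes the
#' corresponding cut, so candidates missing either residue are screened out.
#'
#' @param candidate Candidate protein sequence.
#' @param reference Reference Cas9 sequence carrying the canonical residues.
#' @param requirements Data frame with columns `position` (1-based reference
#'   position) and `residue` (required letter); default D10 + H840.
#' @param params An [align_params()] object.
#' @return List with `pass` (logical) and `sites`, a data frame `position`,
#'   `required`, `mapped_position`, `observed`, `ok`.
#' @export
has_catalytic_residues <- function(candidate, reference,
                                   requirements = data.frame(
                                     position = c(10L, 840L),
                                     residue = c("D", "H")),
                                   params = align_params()) {
  stopifnot(all(requirements$position >= 1))
  mapped <- map_positions(candidate, reference, requirements$position, params)
  cand_chars <- strsplit(candidate, "")[[1]]
  observed <- ifelse(is.na(mapped), NA_character_, cand_chars[mapped])
  ok <- !is.na(observed) & observed == requirements$residue
  list(pass = all(ok),
       sites = data.frame(position = requirements$position,
                          required = requirements$residue,
                          mapped_position = unname(mapped),
                          observed = observed, ok = ok,
                          stringsAsFactors = FALSE))
}

#' Screen a set of candidates
#'
#' @param candidates Named character vector of candidate sequences.
#' @param reference Reference sequence.
#' @param requirements,params As in [has_catalytic_residues()].
#' @return Data frame with one row per candidate: `protein_id`, `pass`, and
#'   the observed residue at each required site.
#' @export
screen_candidates <- function(candidates, reference,
                              requirements = data.frame(position = c(10L, 840L),
                                                        residue = c("D", "H")),
                              params = align_params()) {
  rows <- lapply(names(candidates), function(id) {
    r <- has_catalytic_residues(candidates[[id]], reference, requirements, params)
    obs <- setNames(as.list(r$sites$observed),
                    paste0("residue_", r$sites$position))
    cbind(data.frame(protein_id = id, pass = r$pass, stringsAsFactors = FALSE),
          as.data.frame(obs, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
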