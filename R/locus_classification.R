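#' Load the signature-gene map
#'
#' The map drives type/subtype assignment: each known family carries a type,
#' an optional subtype, and a role (`type_signature`, `subtype_signature`,
#' `generic`). Subtype II-C deliberately has no signature family; it is
#' defined by the exact known-cas composition \{cas9, cas1, cas2\} and called
#' only from complete genomes, because absence evidence is unreliable on
#' fragmented assemblies.
#'
#' @param path YAML file; `NULL` loads the map shipped with the package.
#' @return A list of class `signature_map` with elements `types`, `subtypes`
#'   and `families`.
#' @export
load_signature_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "signature_map.yaml", package = "casforge")
  }
  sm <- yaml::read_yaml(path)
  stopifnot(is.list(sm$families), length(sm$families) > 0)
  structure(sm, class = "signature_map")
}

#' Load the toxin/antitoxin family configuration
#'
#' @param path YAML file with `toxins`, `antitoxins` and `other_known`
#'   entries; `NULL` loads the shipped defaults.
#' @return A list with character vectors `toxins`, `antitoxins`, `other_known`.
#' @export
load_ta_families <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ta_families.yaml", package = "casforge")
  }
  yaml::read_yaml(path)
}

#' Assign CRISPR-Cas types and subtypes to a locus
#'
#' A subtype is called iff its signature family is among the locus's known
#' cas annotations (for cas4 / II-B, only when cas9 is also present). II-C is
#' the exception: it is called iff the locus sits on a complete genome and
#' its known-cas composition is exactly \{cas9, cas1, cas2\}. Types are the
#' parents of called subtypes plus any type-signature evidence (e.g. cas3
#' calls type I even when no subtype resolves).
#'
#' @param locus A locus from [assemble_loci()].
#' @param annotations Named character vector, protein_id -> family_id, for
#'   the locus's SEED/RECRUITED members (see [annotate_proteins()]).
#' @param sigmap A [load_signature_map()] object.
#' @param known_families Extra family ids that are recognized but carry no
#'   type signal (toxins, transposases, ...); families outside the map and
#'   this set trigger a warning and are ignored.
#' @return A list of class `subtype_call` with `locus_id`, `types`,
#'   `subtypes`, `evidence` (subtype -> signature families found) and empty
#'   `cooccurrence_flags`.
#' @export
assign_types <- function(locus, annotations, sigmap = load_signature_map(),
                         known_families = unlist(load_ta_families(), use.names = FALSE)) {
  known_ids <- locus$members$protein_id[locus$members$label %in%
                                          c("SEED_KNOWN", "RECRUITED_KNOWN")]
  fams <- unname(annotations[intersect(names(annotations), known_ids)])
  fams <- fams[!is.na(fams)]
  unknown <- setdiff(fams, c(names(sigmap$families), known_families))
  if (length(unknown) > 0) {
    warning("unknown family id(s) ignored: ", paste(unique(unknown), collapse = ", "))
    fams <- setdiff(fams, unknown)
  }
  fams <- unique(fams)
  subtypes <- character(0)
  evidence <- list()
  for (fam in fams) {
    info <- sigmap$families[[fam]]
    if (is.null(info) || is.null(info$subtype) || info$role != "subtype_signature") next
    if (!is.null(info$requires) && !(info$requires %in% fams)) next
    subtypes <- c(subtypes, info$subtype)
    evidence[[info$subtype]] <- c(evidence[[info$subtype]], fam)
  }
  # II-C: exact minimal type II composition, complete genomes only
  if (identical(sort(fams), sort(c("cas9", "cas1", "cas2"))) &&
      locus$completeness == "COMPLETE_GENOME") {
    subtypes <- c(subtypes, "II-C")
    evidence[["II-C"]] <- c("cas9", "cas1", "cas2")
  }
  subtypes <- unique(subtypes)
  parent <- function(s) sigmap$families[[
    names(which(vapply(sigmap$families, function(f)
      identical(f$subtype, s), logical(1))))[1]]]$type
  types <- unique(unlist(lapply(subtypes, function(s) {
    if (s == "II-C") "II" else parent(s)
  })))
  type_sig <- vapply(fams, function(fam) {
    info <- sigmap$families[[fam]]
    !is.null(info) && identical(info$role, "type_signature")
  }, logical(1))
  types <- unique(c(types, unlist(lapply(fams[type_sig], function(fam)
    sigmap$families[[fam]]$type))))
  structure(list(locus_id = locus$locus_id, types = types, subtypes = subtypes,
                 evidence = evidence, cooccurrence_flags = character(0),
                 families = fams),
            class = "subtype_call")
}

#' Flag cross-type signature co-occurrence within a locus
#'
#' Loci carrying a cas9 gene together with type I or III signature genes (or
#' any multi-type signature combination) are flagged: `"II+I-F"` when cas9
#' co-occurs with a subtype I-F signature, `"I+III"` for a locus carrying
#' both type I and type III type-signatures, etc.
#'
#' @param call A `subtype_call` from [assign_types()].
#' @param sigmap A [load_signature_map()] object.
#' @return The call with `cooccurrence_flags` filled in.
#' @export
detect_cooccurrence <- function(call, sigmap = load_signature_map()) {
  flags <- character(0)
  fams <- call$families
  if ("cas9" %in% fams) {
    for (fam in setdiff(fams, "cas9")) {
      info <- sigmap$families[[fam]]
      if (is.null(info) || is.null(info$type) || identical(info$type, "II")) next
      if (identical(info$role, "subtype_signature")) {
        flags <- c(flags, paste0("II+", info$subtype))
      } else if (identical(info$role, "type_signature")) {
        flags <- c(flags, paste0("II+", info$type))
      }
    }
  }
  if (length(call$types) > 1) {
    ts <- sort(call$types)
    for (i in seq_len(length(ts) - 1)) {
      for (j in seq(i + 1, length(ts))) {
        flags <- c(flags, paste0(ts[i], "+", ts[j]))
      }
    }
  }
  call$cooccurrence_flags <- unique(flags)
  call
}

#' Majority strand of a locus's known cas genes
#'
#' @param locus A locus.
#' @param genes The gene table.
#' @return `"+"`, `"-"`, or `NA` on a tie (no cas-strand majority).
#' @export
locus_cas_strand <- function(locus, genes) {
  ids <- locus$members$protein_id[locus$members$label %in%
                                    c("SEED_KNOWN", "RECRUITED_KNOWN")]
  strands <- genes$strand[match(ids, genes$protein_id)]
  n_plus <- sum(strands == "+")
  n_minus <- sum(strands == "-")
  if (n_plus == n_minus) NA_character_ else if (n_plus > n_minus) "+" else "-"
}

#' Detect toxin-antitoxin gene pairs within a locus
#'
#' Reports every (antitoxin, toxin) member pair at most two genes apart,
#' together with whether the antitoxin lies upstream of the toxin relative
#' to the cas genes' transcription direction, and whether each member shares
#' the locus's majority cas strand. A strand tie leaves the orientation
#' fields `NA` (indeterminate).
#'
#' @param locus A locus.
#' @param genes The gene table.
#' @param annotations Named character vector protein_id -> family_id covering
#'   the locus members (typically from a full-database annotation pass).
#' @param ta A [load_ta_families()] configuration.
#' @param max_gap Maximum `gene_index` separation to call a pair (default 2).
#' @return Data frame: `antitoxin_protein_id`, `toxin_protein_id`,
#'   `antitoxin_family`, `toxin_family`, `antitoxin_upstream`,
#'   `antitoxin_same_strand`, `toxin_same_strand`.
#' @export
detect_toxin_antitoxin <- function(locus, genes, annotations,
                                   ta = load_ta_families(), max_gap = 2L) {
  mem <- locus$members
  fam <- annotations[mem$protein_id]
  anti <- mem[which(fam %in% ta$antitoxins), , drop = FALSE]
  tox <- mem[which(fam %in% ta$toxins), , drop = FALSE]
  out <- data.frame(antitoxin_protein_id = character(0), toxin_protein_id = character(0),
                    antitoxin_family = character(0), toxin_family = character(0),
                    antitoxin_upstream = logical(0), antitoxin_same_strand = logical(0),
                    toxin_same_strand = logical(0), stringsAsFactors = FALSE)
  if (nrow(anti) == 0 || nrow(tox) == 0) return(out)
  cas_strand <- locus_cas_strand(locus, genes)
  for (i in seq_len(nrow(anti))) {
    for (j in seq_len(nrow(tox))) {
      if (abs(anti$gene_index[i] - tox$gene_index[j]) > max_gap) next
      sa <- genes$strand[match(anti$protein_id[i], genes$protein_id)]
      st <- genes$strand[match(tox$protein_id[j], genes$protein_id)]
      upstream <- if (is.na(cas_strand)) NA else if (cas_strand == "+") {
        anti$gene_index[i] < tox$gene_index[j]
      } else {
        anti$gene_index[i] > tox$gene_index[j]
      }
      out <- rbind(out, data.frame(
        antitoxin_protein_id = anti$protein_id[i], toxin_protein_id = tox$protein_id[j],
        antitoxin_family = unname(fam[anti$protein_id[i]]),
        toxin_family = unname(fam[tox$protein_id[j]]),
        antitoxin_upstream = upstream,
        antitoxin_same_strand = if (is.na(cas_strand)) NA else sa == cas_strand,
        toxin_same_strand = if (is.na(cas_strand)) NA else st == cas_strand,
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Fraction of a family's locus members on the strand opposite the cas genes
#'
#' For every locus member annotated with `family_id`, compares the member's
#' strand to the locus's majority cas strand; members in tied loci are
#' skipped. Used for the transposase strand-opposition statistic.
#'
#' @param loci List of loci.
#' @param genes The gene table.
#' @param annotations Named character vector protein_id -> family_id.
#' @param family_id Family to tally.
#' @return List with `n_opposite`, `n_total`, `fraction`, and `percent`
#'   (integer percent, half-up rounding).
#' @export
strand_opposition_fraction <- function(loci, genes, annotations, family_id) {
  n_opp <- 0L
  n_tot <- 0L
  for (locus in loci) {
    cas_strand <- locus_cas_strand(locus, genes)
    if (is.na(cas_strand)) next
    ids <- locus$members$protein_id[annotations[locus$members$protein_id] %in% family_id]
    if (length(ids) == 0) next
    strands <- genes$strand[match(ids, genes$protein_id)]
    n_tot <- n_tot + length(ids)
    n_opp <- n_opp + sum(strands != cas_strand)
  }
  if (n_tot == 0L) stop("no locus member annotated with family ", family_id)
  list(n_opposite = n_opp, n_total = n_tot, fraction = n_opp / n_tot,
       percent = percent_round(n_opp / n_tot))
}
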