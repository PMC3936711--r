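#' Recruitment parameters
#'
#' @param window Neighborhood radius in genes (default 3: a gene can be
#'   recruited when it lies within three genes on either side of an
#'   already-labeled cas gene). Most known cas loci have at least three
#'   genes, which motivates the default.
#' @param weak_e_max Maximum E-value for a weak similarity to count
#'   (default 0.001).
#' @return A list of class `recruitment_params`.
#' @export
recruitment_params <- function(window = 3L, weak_e_max = 1e-3) {
  stopifnot(window >= 1, weak_e_max > 0)
  structure(list(window = as.integer(window), weak_e_max = weak_e_max),
            class = "recruitment_params")
}

#' Find seed cas genes
#'
#' Seeds are the proteins with at least one hit at a Cas family's gathering
#' (trusted) cutoff — the confident similarity assignments that initiate
#' neighborhood recruitment.
#'
#' @param hits Best-hit-reduced hit table (see [read_hit_table()]).
#' @return Character vector of seed protein ids.
#' @export
find_seeds <- function(hits) {
  unique(hits$protein_id[hits$meets_gathering])
}

#' Iteratively recruit weakly similar genes around seeds
#'
#' A non-seed gene is recruited when it has some hit with
#' `e_value <= weak_e_max` and lies within `window` genes (by `gene_index`,
#' same replicon) of an already labeled gene. Recruited genes act as seeds
#' for further recruitment; the procedure repeats until no more genes can be
#' recruited, giving the unique least fixed point (independent of visiting
#' order).
#'
#' @param genes Gene table.
#' @param hits Best-hit-reduced hit table against Cas families.
#' @param seeds Seed protein ids from [find_seeds()].
#' @param params A [recruitment_params()] object.
#' @return Named character vector protein_id -> label (`"SEED_KNOWN"` or
#'   `"RECRUITED_KNOWN"`).
#' @export
recruit_iteratively <- function(genes, hits, seeds, params = recruitment_params()) {
  missing_seed <- setdiff(seeds, genes$protein_id)
  if (length(missing_seed) > 0) {
    stop("seed protein absent from gene table: ", missing_seed[1])
  }
  weak_ok <- unique(hits$protein_id[hits$e_value <= params$weak_e_max])
  labels <- setNames(rep("SEED_KNOWN", length(seeds)), seeds)
  # iterate per replicon over candidate genes with an eligible weak hit
  for (rep_id in unique(genes$replicon_id)) {
    g <- genes[genes$replicon_id == rep_id, , drop = FALSE]
    labeled <- g$protein_id %in% seeds
    candidate <- !labeled & g$protein_id %in% weak_ok
    repeat {
      if (!any(labeled)) break
      lab_idx <- g$gene_index[labeled]
      reach <- vapply(g$gene_index, function(i) any(abs(lab_idx - i) <= params$window),
                      logical(1))
      newly <- candidate & !labeled & reach
      if (!any(newly)) break
      labeled <- labeled | newly
    }
    recruited <- labeled & !(g$protein_id %in% seeds)
    if (any(recruited)) {
      labels[g$protein_id[recruited]] <- "RECRUITED_KNOWN"
    }
  }
  labels
}

#' Best-hit annotation per protein
#'
#' Resolves each protein to the family of its best hit: lowest E-value, ties
#' broken by higher bit score, then lexicographic family id. Used both for
#' subtype evidence and for the provisional annotation of recruited genes.
#'
#' @param hits Hit table.
#' @return Named character vector protein_id -> family_id.
#' @export
annotate_proteins <- function(hits) {
  if (nrow(hits) == 0) return(setNames(character(0), character(0)))
  h <- hits[order(hits$protein_id, hits$e_value, -hits$bit_score, hits$family_id), ]
  h <- h[!duplicated(h$protein_id), ]
  setNames(h$family_id, h$protein_id)
}

#' Assemble labeled genes into cas loci
#'
#' Per replicon, labeled genes are grouped into maximal chains in which
#' consecutive labeled genes are at most `window` apart in `gene_index`;
#' unlabeled genes strictly inside a chain's span are added as
#' `INTERVENING_UNKNOWN` members. Chains without a single seed member are
#' discarded. Chains never cross replicon/contig boundaries.
#'
#' @param genes Gene table.
#' @param labels Labels from [recruit_iteratively()].
#' @param completeness `"COMPLETE_GENOME"` or `"DRAFT_OR_CONTIG"`; carried on
#'   each locus because it gates the II-C subtype call.
#' @param params A [recruitment_params()] object.
#' @return List of loci; each a list with `locus_id`, `replicon_id`,
#'   `first_index`, `last_index`, `completeness` and a `members` data frame
#'   (`protein_id`, `gene_index`, `label`).
#' @export
assemble_loci <- function(genes, labels, completeness = c("DRAFT_OR_CONTIG", "COMPLETE_GENOME"),
                          params = recruitment_params()) {
  completeness <- match.arg(completeness)
  stopifnot(length(labels) > 0)
  loci <- list()
  for (rep_id in unique(genes$replicon_id)) {
    g <- genes[genes$replicon_id == rep_id, , drop = FALSE]
    g <- g[order(g$gene_index), , drop = FALSE]
    lab <- g[g$protein_id %in% names(labels), , drop = FALSE]
    if (nrow(lab) == 0) next
    breaks <- which(diff(lab$gene_index) > params$window)
    chain_id <- cumsum(c(1L, seq_len(nrow(lab) - 1) %in% breaks))
    k <- 0L
    for (ch in split(seq_len(nrow(lab)), chain_id)) {
      first <- lab$gene_index[ch[1]]
      last <- lab$gene_index[ch[length(ch)]]
      span <- g[g$gene_index >= first & g$gene_index <= last, , drop = FALSE]
      member_label <- ifelse(span$protein_id %in% names(labels),
                             labels[span$protein_id], "INTERVENING_UNKNOWN")
      if (!any(member_label == "SEED_KNOWN")) next
      k <- k + 1L
      loci[[length(loci) + 1L]] <- list(
        locus_id = sprintf("%s_L%02d", rep_id, k),
        replicon_id = rep_id, first_index = first, last_index = last,
        completeness = completeness,
        members = data.frame(protein_id = span$protein_id,
                             gene_index = span$gene_index,
                             label = unname(member_label),
                             stringsAsFactors = FALSE))
    }
  }
  loci
}

#' Collect novel-Cas candidates from intervening unknowns
#'
#' Intervening unknown genes whose proteins have no hit of any kind against
#' the full family database are the novel-family candidates; intervening
#' genes that do carry a known (even non-Cas) annotation are routed to the
#' assorted-functions report instead.
#'
#' @param loci Loci from [assemble_loci()].
#' @param all_family_hits Hit table against the full family database
#'   (Cas and non-Cas families alike).
#' @return List with `candidates` (character vector of protein ids) and
#'   `assorted` (data frame `protein_id`, `family_id` of annotated
#'   intervening genes).
#' @export
collect_novel_candidates <- function(loci, all_family_hits) {
  inter <- unlist(lapply(loci, function(l)
    l$members$protein_id[l$members$label == "INTERVENING_UNKNOWN"]), use.names = FALSE)
  inter <- unique(inter)
  annotated <- intersect(inter, unique(all_family_hits$protein_id))
  ann <- annotate_proteins(all_family_hits[all_family_hits$protein_id %in% annotated, ,
                                           drop = FALSE])
  list(candidates = setdiff(inter, annotated),
       assorted = data.frame(protein_id = names(ann), family_id = unname(ann),
                             stringsAsFactors = FALSE))
}

#' Run the full locus-detection stage
#'
#' Convenience wrapper chaining [find_seeds()], [recruit_iteratively()] and
#' [assemble_loci()].
#'
#' @param genes Gene table.
#' @param hits Hit table against Cas families.
#' @param completeness Passed to [assemble_loci()].
#' @param params A [recruitment_params()] object.
#' @return List with `seeds`, `labels` and `loci`.
#' @export
detect_cas_loci <- function(genes, hits,
                            completeness = c("DRAFT_OR_CONTIG", "COMPLETE_GENOME"),
                            params = recruitment_params()) {
  completeness <- match.arg(completeness)
  seeds <- find_seeds(hits)
  if (length(seeds) == 0) {
    return(list(seeds = character(0), labels = setNames(character(0), character(0)),
                loci = list()))
  }
  labels <- recruit_iteratively(genes, hits, seeds, params)
  list(seeds = seeds, labels = labels,
       loci = assemble_loci(genes, labels, completeness, params))
}
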