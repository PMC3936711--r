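#' Build and validate a gene table
#'
#' The gene table is the package's central annotation container: one row per
#' gene, ordered by genomic start within each replicon, with `gene_index` the
#' 0-based rank of the gene in that order. Gene-count distance on
#' `gene_index` is the only distance used by the neighborhood recruitment.
#'
#' @param df A data.frame with columns `replicon_id`, `start`, `end`,
#'   `strand`, `protein_id` and optionally `product`.
#' @return A validated data.frame with `gene_index` assigned, sorted by
#'   `(replicon_id, start)`.
#' @export
gene_table <- function(df) {
  req <- c("replicon_id", "start", "end", "strand", "protein_id")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("gene table missing columns: ", paste(miss, collapse = ", "))
  if (!"product" %in% names(df)) df$product <- rep(NA_character_, nrow(df))
  if (nrow(df) == 0) {
    df$gene_index <- integer(0)
    return(df[, c("replicon_id", "gene_index", "start", "end", "strand", "protein_id", "product")])
  }
  if (!is.numeric(df$start) || !is.numeric(df$end) ||
      any(df$start != floor(df$start)) || any(df$end != floor(df$end))) {
    stop("non-integer coordinates in gene table")
  }
  bad <- which(df$start > df$end)
  if (length(bad) > 0) stop("start > end at row ", bad[1])
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(df$protein_id)) {
    stop("duplicate protein_id: ", df$protein_id[duplicated(df$protein_id)][1])
  }
  df <- df[order(df$replicon_id, df$start), , drop = FALSE]
  df$gene_index <- as.integer(unlist(
    lapply(split(seq_len(nrow(df)), df$replicon_id), function(i) seq_along(i) - 1L),
    use.names = FALSE))
  # split() orders groups by factor level == sorted replicon_id, matching row order
  rownames(df) <- NULL
  df[, c("replicon_id", "gene_index", "start", "end", "strand", "protein_id", "product")]
}

#' Read gene annotations from GFF3 or TSV
#'
#' @param path File path.
#' @param dialect `"tsv"` (columns `replicon_id`, `start`, `end`, `strand`,
#'   `protein_id`, optional `product`) or `"gff3"` (CDS/gene features; the
#'   `ID` attribute becomes `protein_id`).
#' @return A gene table (see [gene_table()]).
#' @export
read_gene_table <- function(path, dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    first <- readLines(path, n = 1L)
    if (length(first) == 0 || !nzchar(first)) {
      return(gene_table(data.frame(replicon_id = character(0), start = integer(0),
                                   end = integer(0), strand = character(0),
                                   protein_id = character(0))))
    }
    df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    for (col in c("start", "end")) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      if (anyNA(v)) stop("malformed coordinate at line ", which(is.na(v))[1] + 1L)
      df[[col]] <- v
    }
    bad <- which(df$start > df$end)
    if (length(bad) > 0) stop("start > end at line ", bad[1] + 1L)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gd <- as.data.frame(gr, stringsAsFactors = FALSE)
    gd <- gd[as.character(gd$type) %in% c("CDS", "gene"), , drop = FALSE]
    ids <- as.character(gd$ID)
    if (anyNA(ids)) stop("GFF3 feature without ID attribute")
    df <- data.frame(replicon_id = as.character(gd$seqnames),
                     start = gd$start, end = gd$end,
                     strand = as.character(gd$strand),
                     protein_id = ids, stringsAsFactors = FALSE)
    if ("product" %in% names(gd)) df$product <- as.character(gd$product)
  }
  gene_table(df)
}

#' Write a gene table
#'
#' @param genes A gene table.
#' @param path Output path.
#' @param dialect `"tsv"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path, dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    out <- genes[, c("replicon_id", "start", "end", "strand", "protein_id", "product")]
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  } else {
    lines <- c("##gff-version 3",
               sprintf("%s\tcasforge\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                       genes$replicon_id, genes$start, genes$end,
                       genes$strand, genes$protein_id))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a protein-vs-family hit table
#'
#' Mirrors tabular protein-to-profile search output: one row per hit with a
#' bit score, an E-value, and a flag saying whether the hit met the family's
#' gathering (trusted) cutoff. Duplicated `(protein, family)` rows are
#' reduced to the best hit (lowest E-value; ties broken by higher bit score).
#'
#' @param path TSV with header columns `protein_id`, `family_id`,
#'   `bit_score`, `e_value`, `meets_gathering`.
#' @return A data.frame of best hits.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0 || !nzchar(first)) return(empty_hits())
  df <- read.delim(path, stringsAsFactors = FALSE)
  hit_table(df)
}

empty_hits <- function() {
  data.frame(protein_id = character(0), family_id = character(0),
             bit_score = numeric(0), e_value = numeric(0),
             meets_gathering = logical(0), stringsAsFactors = FALSE)
}

#' Validate a hit table and reduce to best hit per (protein, family)
#' @param df Data frame with the hit-table columns.
#' @return Validated, best-hit-reduced data.frame.
#' @export
hit_table <- function(df) {
  req <- c("protein_id", "family_id", "bit_score", "e_value", "meets_gathering")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("hit table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(empty_hits())
  if (is.character(df$meets_gathering)) {
    tok <- toupper(df$meets_gathering)
    if (!all(tok %in% c("TRUE", "FALSE", "T", "F", "1", "0"))) {
      stop("unknown boolean token in meets_gathering")
    }
    df$meets_gathering <- tok %in% c("TRUE", "T", "1")
  }
  if (any(df$e_value < 0)) stop("negative e_value in hit table")
  df <- df[order(df$protein_id, df$family_id, df$e_value, -df$bit_score), , drop = FALSE]
  df <- df[!duplicated(df[, c("protein_id", "family_id")]), , drop = FALSE]
  rownames(df) <- NULL
  df[, req]
}

#' Write a hit table
#' @param hits Hit table data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file; the first whitespace-delimited header token is the
#'   protein id.
#' @return Named character vector of upper-case amino-acid sequences with
#'   terminal `*` stripped.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(ss))
  seqs <- gsub("^\\*+|\\*+$", "", seqs)
  if (any(!nzchar(seqs))) stop("empty sequence: ", ids[!nzchar(seqs)][1])
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Write the per-locus report
#'
#' One TSV row per locus (id, replicon, index span, member counts per label,
#' assigned types/subtypes, evidence families) plus a JSON sidecar carrying
#' the full member lists.
#'
#' @param loci List of loci from [assemble_loci()].
#' @param calls List of subtype calls from [assign_types()]; every call must
#'   reference a locus in `loci`.
#' @param path Output TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_locus_report <- function(loci, calls, path) {
  locus_ids <- vapply(loci, function(l) l$locus_id, character(1))
  call_ids <- vapply(calls, function(cl) cl$locus_id, character(1))
  dangling <- setdiff(call_ids, locus_ids)
  if (length(dangling) > 0) stop("call references unknown locus: ", dangling[1])
  rows <- lapply(loci, function(l) {
    cl <- if (l$locus_id %in% call_ids) calls[[match(l$locus_id, call_ids)]] else NULL
    tab <- table(factor(l$members$label,
                        levels = c("SEED_KNOWN", "RECRUITED_KNOWN", "INTERVENING_UNKNOWN")))
    data.frame(locus_id = l$locus_id, replicon_id = l$replicon_id,
               first_index = l$first_index, last_index = l$last_index,
               n_seed = as.integer(tab[["SEED_KNOWN"]]),
               n_recruited = as.integer(tab[["RECRUITED_KNOWN"]]),
               n_intervening = as.integer(tab[["INTERVENING_UNKNOWN"]]),
               types = if (is.null(cl)) "" else paste(sort(cl$types), collapse = ","),
               subtypes = if (is.null(cl)) "" else paste(sort(cl$subtypes), collapse = ","),
               evidence = if (is.null(cl) || length(cl$evidence) == 0) "" else
                 paste(sprintf("%s:%s", names(cl$evidence),
                               vapply(cl$evidence, paste, character(1), collapse = "|")),
                       collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(locus_id = character(0), replicon_id = character(0),
               first_index = integer(0), last_index = integer(0),
               n_seed = integer(0), n_recruited = integer(0),
               n_intervening = integer(0), types = character(0),
               subtypes = character(0), evidence = character(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- lapply(loci, function(l) {
    list(locus_id = l$locus_id, replicon_id = l$replicon_id,
         first_index = l$first_index, last_index = l$last_index,
         completeness = l$completeness,
         members = l$members)
  })
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
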