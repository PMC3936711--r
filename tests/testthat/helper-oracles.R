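# Independent oracles used to validate the package's algorithms.

# Brute-force BFS reachability over the "weak hit within window" relation:
# the expected label set of the neighborhood recruitment.
oracle_recruit <- function(genes, hits, seeds, window = 3, weak_e_max = 1e-3) {
  weak <- unique(hits$protein_id[hits$e_value <= weak_e_max])
  labeled <- seeds
  frontier <- seeds
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (p in frontier) {
      gi <- genes[genes$protein_id == p, ]
      nb <- genes$protein_id[genes$replicon_id == gi$replicon_id &
                               abs(genes$gene_index - gi$gene_index) <= window]
      new <- setdiff(intersect(nb, weak), labeled)
      labeled <- c(labeled, new)
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  sort(labeled)
}

# Gotoh affine-gap global alignment returning the optimal raw score, with a
# gap of length k costing gap_open + k * gap_ext (the convention of the
# package's aligner).
oracle_gotoh <- function(a, b, gap_open = 11, gap_ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sm <- get("BLOSUM62", envir = environment())
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in match
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in b (A consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in a (B consumed)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + i * gap_ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + j * gap_ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sm[A[i], B[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive recursive enumeration of all gapped alignments of a sequence to
# profile columns (no memoization), for tiny inputs only.
oracle_profile_score <- function(profile, seq) {
  chars <- strsplit(seq, "")[[1]]
  gp <- profile$gap_penalty
  cols <- profile$columns
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) best <- max(best, rec(i - 1, j - 1) + cols[chars[i], j])
    if (j > 0) best <- max(best, rec(i, j - 1) + gp)
    if (i > 0) best <- max(best, rec(i - 1, j) + gp)
    best
  }
  rec(length(chars), ncol(cols))
}

# Run the reference numpy MCL implementation on a list of similarity graphs.
# Returns a list of partitions (lists of sorted 0-based id vectors).
oracle_mcl <- function(graphs, inflation = 1.4) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  payload <- list(inflation = inflation, graphs = lapply(graphs, function(g) {
    idx <- setNames(seq_along(g$nodes) - 1L, g$nodes)
    list(n = length(g$nodes),
         edges = if (nrow(g$edges) == 0) list() else
           lapply(seq_len(nrow(g$edges)), function(k)
             list(idx[[g$edges$from[k]]], idx[[g$edges$to[k]]], g$edges$weight[k])))
  }))
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA)
  script <- test_path("mcl_reference.py")
  status <- system2("python", c(script, infile, outfile))
  stopifnot(status == 0)
  parts <- jsonlite::read_json(outfile, simplifyVector = FALSE)
  lapply(parts, function(p) lapply(p, function(cl) sort(unlist(cl))))
}

# Canonical form of a partition for comparison: sorted list of sorted members.
canonical_partition <- function(clusters) {
  cl <- lapply(clusters, function(x) sort(as.character(x)))
  cl[order(vapply(cl, `[`, character(1), 1))]
}

# Positional identity between equal-length sequences (no alignment).
positional_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}
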