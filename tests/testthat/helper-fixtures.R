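# Small fixture builders shared across the test files.

# A gene table with one gene per requested index on one replicon (ids p<i>).
make_genes <- function(indices, replicon = "repA", strands = "+") {
  strands <- rep_len(strands, length(indices))
  gene_table(data.frame(replicon_id = replicon,
                        start = 1000 * (indices + 1),
                        end = 1000 * (indices + 1) + 900,
                        strand = strands,
                        protein_id = paste0("p", indices),
                        stringsAsFactors = FALSE))
}

make_hit <- function(protein, family = "cas1", bit = 100, e = 1e-20, ga = TRUE) {
  data.frame(protein_id = protein, family_id = family, bit_score = bit,
             e_value = e, meets_gathering = ga, stringsAsFactors = FALSE)
}

# A hand-built locus object around the given member rows.
make_locus <- function(members, locus_id = "L1", replicon = "repA",
                       completeness = "DRAFT_OR_CONTIG") {
  list(locus_id = locus_id, replicon_id = replicon,
       first_index = min(members$gene_index),
       last_index = max(members$gene_index),
       completeness = completeness, members = members)
}

# Random weak/strong hit tables over a random replicon, for property tests.
random_recruitment_case <- function(seed, max_genes = 30) {
  set.seed(seed)
  n <- sample(5:max_genes, 1)
  genes <- make_genes(0:(n - 1))
  n_seeds <- sample(1:3, 1)
  seed_ids <- sample(genes$protein_id, n_seeds)
  n_weak <- sample(0:(n %/% 2), 1)
  weak_ids <- sample(setdiff(genes$protein_id, seed_ids), n_weak)
  rows <- list()
  for (p in seed_ids) rows[[length(rows) + 1]] <- make_hit(p)
  for (p in weak_ids) {
    rows[[length(rows) + 1]] <- make_hit(p, family = "cas7", bit = 30,
                                         e = 10^runif(1, -6, -3), ga = FALSE)
  }
  hits <- hit_table(do.call(rbind, rows))
  list(genes = genes, hits = hits, seeds = seed_ids)
}

# A random weighted similarity graph on <= max_nodes nodes.
random_graph <- function(seed, max_nodes = 30, p_edge = 0.15) {
  set.seed(seed)
  n <- sample(4:max_nodes, 1)
  nodes <- sprintf("n%02d", seq_len(n))
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (runif(1) < p_edge) {
        edges[[length(edges) + 1]] <- data.frame(
          from = nodes[i], to = nodes[j], weight = runif(1, 50, 300),
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), weight = numeric(0))
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

# Explicit clique graph builder (weights w within cliques, bridges separate).
clique_graph <- function(sizes, w = 100, bridges = NULL) {
  nodes <- character(0)
  edges <- list()
  off <- 0
  for (s in sizes) {
    ids <- sprintf("k%d_n%d", off + 1, seq_len(s))
    for (i in seq_len(s - 1)) {
      for (j in seq(i + 1, s)) {
        edges[[length(edges) + 1]] <- data.frame(from = ids[i], to = ids[j],
                                                 weight = w, stringsAsFactors = FALSE)
      }
    }
    nodes <- c(nodes, ids)
    off <- off + 1
  }
  if (!is.null(bridges)) {
    for (b in bridges) {
      edges[[length(edges) + 1]] <- data.frame(from = b[[1]], to = b[[2]],
                                               weight = as.numeric(b[[3]]),
                                               stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), weight = numeric(0),
               stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges),
            class = "similarity_graph")
}

# Synthetic Cas9-like reference: 900 residues with D at 10 and H at 840.
synth_cas9_reference <- function(seed = 42) {
  set.seed(seed)
  chars <- strsplit(random_protein(900), "")[[1]]
  chars[10] <- "D"
  chars[840] <- "H"
  paste(chars, collapse = "")
}

substitute_at <- function(seq, pos, res) {
  chars <- strsplit(seq, "")[[1]]
  chars[pos] <- res
  paste(chars, collapse = "")
}

random_protein_fixture <- function(len, seed) {
  set.seed(seed)
  random_protein(len)
}
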