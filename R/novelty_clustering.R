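#' Greedy identity-based redundancy reduction
#'
#' CD-HIT-style greedy incremental clustering: sequences are visited in
#' decreasing length order (ties broken by lexicographic id); each sequence
#' joins the first existing representative to which its identity (identical
#' aligned positions over the shorter length) reaches `threshold`, otherwise
#' it becomes a new representative.
#'
#' @param seqs Named character vector of sequences.
#' @param threshold Identity threshold in (0, 1], default 0.90.
#' @param params An [align_params()] object.
#' @return List with `representatives` (ids) and `membership` (named
#'   character vector id -> representative id).
#' @export
reduce_redundancy <- function(seqs, threshold = 0.90, params = align_params()) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(seqs) == 0) {
    return(list(representatives = character(0),
                membership = setNames(character(0), character(0))))
  }
  ord <- order(-nchar(seqs), names(seqs))
  ids <- names(seqs)[ord]
  reps <- character(0)
  membership <- setNames(character(length(ids)), ids)
  for (id in ids) {
    assigned <- FALSE
    for (r in reps) {
      if (pairwise_identity(seqs[[id]], seqs[[r]], params) >= threshold) {
        membership[id] <- r
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, id)
      membership[id] <- id
    }
  }
  list(representatives = reps, membership = membership)
}

#' Build a protein similarity graph at a bit-score threshold
#'
#' Undirected weighted graph with an edge between two sequences iff their
#' pairwise alignment bit score is strictly greater than `bit_threshold`
#' (default 60, the all-vs-all search cut used ahead of Markov clustering).
#'
#' @param seqs Named character vector (>= 1 sequence).
#' @param bit_threshold Bit-score edge threshold.
#' @param params An [align_params()] object.
#' @return A list of class `similarity_graph` with `nodes` and an `edges`
#'   data frame (`from`, `to`, `weight` = bit score).
#' @export
build_graph <- function(seqs, bit_threshold = 60, params = align_params()) {
  stopifnot(length(seqs) >= 1)
  ids <- names(seqs)
  edges <- list()
  n <- length(ids)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        sc <- align_pair(seqs[[i]], seqs[[j]], params)
        if (sc$bit_score > bit_threshold) {
          edges[[length(edges) + 1L]] <- data.frame(
            from = ids[i], to = ids[j], weight = sc$bit_score,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), weight = numeric(0),
               stringsAsFactors = FALSE)
  structure(list(nodes = ids, edges = edges), class = "similarity_graph")
}

#' Markov clustering (MCL) of a similarity graph
#'
#' Simulates random-walk flow on the graph: the column-stochastic transition
#' matrix (with self-loops set to each node's maximum incident edge weight)
#' is alternately expanded (matrix squaring) and inflated (entrywise power
#' followed by column renormalization), with small entries pruned, until the
#' flow converges. Clusters are the connected components of the non-zero
#' structure of the limit matrix. Inflation controls granularity; 1.4 is the
#' default used throughout the package.
#'
#' @param graph A `similarity_graph` from [build_graph()].
#' @param inflation Inflation exponent (> 1), default 1.4.
#' @param prune_tol Entries below this are zeroed each iteration.
#' @param conv_tol Convergence threshold on the max entry change.
#' @param max_iter Iteration cap.
#' @return List of character vectors, one per cluster, partitioning the nodes.
#' @export
mcl <- function(graph, inflation = 1.4, prune_tol = 1e-5, conv_tol = 1e-8,
                max_iter = 100L) {
  stopifnot(inflation > 1)
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0) return(list())
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  if (nrow(e) > 0) {
    for (k in seq_len(nrow(e))) {
      A[e$from[k], e$to[k]] <- e$weight[k]
      A[e$to[k], e$from[k]] <- e$weight[k]
    }
  }
  self <- apply(A, 1, max)
  diag(A) <- ifelse(self > 0, self, 1)
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune_tol] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < conv_tol) break
  }
  B <- (M > 0) | (t(M) > 0)
  gI <- igraph::graph_from_adjacency_matrix(B, mode = "undirected", diag = FALSE)
  comp <- igraph::components(gI)$membership
  unname(lapply(split(nodes, comp), unname))
}

#' Filter MCL clusters into candidate novel families
#'
#' Keeps clusters with at least `min_size` members; a kept family passes the
#' diversity requirement when no member pair exceeds `diversity_max_identity`
#' (evaluated on the members as given, i.e. after upstream redundancy
#' reduction). Small clusters and singletons are routed to a discard table.
#'
#' @param clusters List of clusters from [mcl()].
#' @param seqs Named character vector covering all cluster members.
#' @param min_size Minimum family size (default 5).
#' @param diversity_max_identity Maximum allowed pairwise identity
#'   (default 0.50).
#' @param params An [align_params()] object.
#' @return List with `families` (each: `family_id`, `members`, `passed_size`,
#'   `passed_diversity`, `max_pairwise_identity`, `excluded_known_like` =
#'   `NA` until [exclude_known_like()]) and `discards` (data frame
#'   `protein_id`, `cluster_size`).
#' @export
select_novel_families <- function(clusters, seqs, min_size = 5,
                                  diversity_max_identity = 0.50,
                                  params = align_params()) {
  families <- list()
  discards <- list()
  k <- 0L
  for (cl in clusters) {
    if (length(cl) < min_size) {
      discards[[length(discards) + 1L]] <- data.frame(
        protein_id = cl, cluster_size = length(cl), stringsAsFactors = FALSE)
      next
    }
    max_id <- 0
    for (i in seq_len(length(cl) - 1)) {
      for (j in seq(i + 1, length(cl))) {
        max_id <- max(max_id, pairwise_identity(seqs[[cl[i]]], seqs[[cl[j]]], params))
      }
    }
    k <- k + 1L
    families[[k]] <- list(family_id = sprintf("novel%02d", k), members = cl,
                          passed_size = TRUE,
                          passed_diversity = max_id <= diversity_max_identity,
                          max_pairwise_identity = max_id,
                          excluded_known_like = NA)
  }
  discards <- if (length(discards) > 0) do.call(rbind, discards) else
    data.frame(protein_id = character(0), cluster_size = integer(0),
               stringsAsFactors = FALSE)
  list(families = families, discards = discards)
}

#' Exclude families with residual similarity to known Cas proteins
#'
#' A family is excluded when ANY member matches ANY known reference sequence
#' under the loose joint criterion E-value <= `e_max` AND identity >=
#' `id_min`; families that only meet one of the two conditions are kept.
#'
#' @param families Family list from [select_novel_families()].
#' @param known_seqs Named character vector of known Cas reference sequences.
#' @param seqs Sequences of the family members.
#' @param e_max E-value bound (default 1e-5).
#' @param id_min Identity bound (default 0.30).
#' @param params An [align_params()] object (also supplies the
#'   Karlin-Altschul constants for the E-value).
#' @return The family list with `excluded_known_like` set on every family.
#' @export
exclude_known_like <- function(families, known_seqs, seqs, e_max = 1e-5,
                               id_min = 0.30, params = align_params()) {
  if (length(known_seqs) == 0) {
    warning("empty known-Cas reference set: no exclusions applied")
    return(lapply(families, function(f) {
      f$excluded_known_like <- FALSE
      f
    }))
  }
  lapply(families, function(f) {
    excl <- FALSE
    for (m in f$members) {
      for (kn in names(known_seqs)) {
        sc <- align_pair(seqs[[m]], known_seqs[[kn]], params)
        ev <- alignment_evalue(sc$raw_score, nchar(seqs[[m]]),
                               nchar(known_seqs[[kn]]), params)
        if (ev <= e_max && sc$identity >= id_min) {
          excl <- TRUE
          break
        }
      }
      if (excl) break
    }
    f$excluded_known_like <- excl
    f
  })
}
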