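#' Drop length outliers from a family
#'
#' Excludes sequences whose length is two population standard deviations or
#' more away from the family's mean length (both tails). When the SD is zero
#' every length equals the mean and nothing is excluded.
#'
#' @param seqs Named character vector (>= 3 sequences; the rule is
#'   meaningless below that).
#' @return The retained subset.
#' @export
drop_length_outliers <- function(seqs) {
  if (length(seqs) < 3) stop("need at least 3 sequences for the 2-SD length rule")
  lens <- nchar(seqs)
  m <- mean(lens)
  s <- sqrt(mean((lens - m)^2))
  keep <- abs(lens - m) < 2 * s | lens == m
  seqs[keep]
}

#' Center-star multiple alignment
#'
#' The center is the sequence maximizing the summed pairwise alignment raw
#' scores against all others; the remaining sequences are merged onto the
#' center one at a time under the "once a gap, always a gap" rule.
#'
#' @param seqs Named character vector (>= 2, or 1 for a trivial alignment).
#' @param params An [align_params()] object.
#' @return A character matrix, one row per sequence (rownames = ids), one
#'   column per alignment column; `"-"` denotes a gap.
#' @export
star_align <- function(seqs, params = align_params()) {
  if (length(seqs) == 1) {
    m <- matrix(strsplit(seqs[[1]], "")[[1]], nrow = 1)
    rownames(m) <- names(seqs)
    return(m)
  }
  n <- length(seqs)
  ids <- names(seqs)
  score_sum <- numeric(n)
  alns <- vector("list", n)  # alns[[c]][[j]]: alignment of j against center c
  for (i in seq_len(n)) {
    total <- 0
    row <- vector("list", n)
    for (j in seq_len(n)) {
      if (i == j) next
      a <- align_pair(seqs[[j]], seqs[[i]], params)
      total <- total + a$raw_score
      row[[j]] <- a
    }
    score_sum[i] <- total
    alns[[i]] <- row
  }
  ci <- which.max(score_sum)
  center <- strsplit(seqs[[ci]], "")[[1]]
  # master: center with accumulated gap columns; rows built against it
  master <- center
  rows <- list()
  rows[[ids[ci]]] <- center
  for (j in seq_len(n)) {
    if (j == ci) next
    a <- alns[[ci]][[j]]
    pj <- strsplit(a$aligned_a, "")[[1]]  # sequence j, gapped
    pc <- strsplit(a$aligned_b, "")[[1]]  # center, gapped
    # walk master and pairwise center in parallel, merging insertion columns
    new_master <- character(0)
    new_row <- character(0)
    upd <- lapply(rows, function(r) character(0))
    mi <- 1L
    pi <- 1L
    while (mi <= length(master) || pi <= length(pc)) {
      m_gap <- mi <= length(master) && master[mi] == "-"
      p_ins <- pi <= length(pc) && pc[pi] == "-"
      if (mi > length(master)) {         # trailing insertion in pairwise
        new_master <- c(new_master, "-")
        new_row <- c(new_row, pj[pi])
        upd <- lapply(upd, function(r) c(r, "-"))
        pi <- pi + 1L
      } else if (pi > length(pc)) {      # trailing master gap columns
        new_master <- c(new_master, master[mi])
        new_row <- c(new_row, "-")
        for (nm in names(rows)) upd[[nm]] <- c(upd[[nm]], rows[[nm]][mi])
        mi <- mi + 1L
      } else if (m_gap && !p_ins) {      # master-only gap column
        new_master <- c(new_master, "-")
        new_row <- c(new_row, "-")
        for (nm in names(rows)) upd[[nm]] <- c(upd[[nm]], rows[[nm]][mi])
        mi <- mi + 1L
      } else if (p_ins) {                # insertion relative to center
        new_master <- c(new_master, "-")
        new_row <- c(new_row, pj[pi])
        upd <- lapply(upd, function(r) c(r, "-"))
        pi <- pi + 1L
      } else {                           # both consume a center residue
        new_master <- c(new_master, master[mi])
        new_row <- c(new_row, pj[pi])
        for (nm in names(rows)) upd[[nm]] <- c(upd[[nm]], rows[[nm]][mi])
        mi <- mi + 1L
        pi <- pi + 1L
      }
    }
    master <- new_master
    rows <- upd
    rows[[ids[j]]] <- new_row
  }
  out <- do.call(rbind, rows[ids])
  rownames(out) <- ids
  out
}

#' Build a position-specific scoring model from an alignment
#'
#' Per retained column, the model stores log-odds in bits:
#' `log2((count_r + pseudocount * bg_r) / (n + pseudocount) / bg_r)` for each
#' residue `r`, where `n` is the number of rows. Columns with more than 50%
#' gaps are dropped from the model.
#'
#' @param alignment Character matrix from [star_align()].
#' @param background Named residue frequency vector (default uniform).
#' @param pseudocount Positive pseudocount (default 1); required > 0.
#' @param gap_penalty Per-column score (bits) for skipping a model column or
#'   inserting an unmodeled residue (default -4).
#' @return A list of class `profile_model`: `columns` (20 x m log-odds
#'   matrix), `background`, `gap_penalty`, `seed_ids`, and unset cutoffs
#'   (`gathering_cutoff`, `trusted_cutoff`, `noise_cutoff` = `NA`),
#'   `n_iterations = 0`.
#' @export
build_profile <- function(alignment, background = NULL, pseudocount = 1,
                          gap_penalty = -4) {
  stopifnot(is.matrix(alignment), ncol(alignment) >= 1)
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  aa <- amino_acids()
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), aa)
  n <- nrow(alignment)
  gap_frac <- colMeans(alignment == "-")
  keep <- which(gap_frac <= 0.5)
  cols <- matrix(0, 20, length(keep), dimnames = list(aa, NULL))
  for (k in seq_along(keep)) {
    col <- alignment[, keep[k]]
    cnt <- table(factor(col[col != "-"], levels = aa))
    cols[, k] <- log2((as.numeric(cnt) + pseudocount * background[aa]) /
                        (n + pseudocount) / background[aa])
  }
  structure(list(columns = cols, background = background,
                 gap_penalty = gap_penalty, seed_ids = rownames(alignment),
                 gathering_cutoff = NA_real_, trusted_cutoff = NA_real_,
                 noise_cutoff = NA_real_, n_iterations = 0L),
            class = "profile_model")
}

#' Score a sequence against a profile
#'
#' Global dynamic-programming alignment of the sequence to the profile
#' columns: each matched column contributes its log-odds for the residue,
#' and every skipped column or inserted residue costs the profile's gap
#' penalty. Returns the best total score in bits.
#'
#' @param profile A `profile_model`.
#' @param seq Non-empty amino-acid sequence.
#' @return The optimal alignment score (bits).
#' @export
score_sequence <- function(profile, seq) {
  if (!nzchar(seq)) stop("cannot score an empty sequence")
  m <- ncol(profile$columns)
  stopifnot(m >= 1)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  gp <- profile$gap_penalty
  aa <- rownames(profile$columns)
  # emission score per (residue position, column)
  idx <- match(chars, aa)
  unknown_score <- log2(1 / (nrow_profile_n(profile) + 1))
  S_prev <- gp * (0:L)          # column 0: all-insert prefix
  gline <- gp * (0:L)
  for (j in seq_len(m)) {
    col <- profile$columns[, j]
    emit <- ifelse(is.na(idx), unknown_score, col[idx])
    # best score ending at column j before any insertion: match or delete
    V <- c(S_prev[1] + gp,
           pmax(S_prev[seq_len(L)] + emit, S_prev[seq_len(L) + 1L] + gp))
    # insertions extend any prefix at cost gp each: running max via cummax
    S_prev <- gline + cummax(V - gline)
  }
  S_prev[L + 1]
}

# effective n used for unknown-residue emission (pseudocount-only odds)
nrow_profile_n <- function(profile) length(profile$seed_ids)

#' Refine a family profile by recruit-above-worst-seed iteration
#'
#' Builds a profile from the current seed set, scores every database
#' sequence, and recruits those scoring strictly above the worst-scoring
#' current seed; each iteration adds the recruits, removes the single
#' worst-scoring seed (which returns to the database pool and may be
#' re-recruited later), and rebuilds. Iteration stops when no new sequence
#' is recruited. On termination the lowest final-seed score is recorded as
#' the gathering and trusted cutoff, and the highest score among sequences
#' not in the final seed set as the noise cutoff.
#'
#' @param seed_seqs Named character vector of seed sequences (after
#'   [drop_length_outliers()]).
#' @param database_seqs Named character vector of database sequences
#'   (ids disjoint from the current seeds are scored; removed seeds rejoin
#'   the pool).
#' @param background,pseudocount,gap_penalty Passed to [build_profile()].
#' @param params An [align_params()] object for the seed alignment.
#' @param max_iter Safety cap on iterations.
#' @return A `profile_model` with cutoffs, final `seed_ids` and
#'   `n_iterations` set; `noise_cutoff` is `-Inf` when every database
#'   sequence was recruited and `NA` when the database was empty.
#' @export
refine_profile <- function(seed_seqs, database_seqs,
                           background = NULL, pseudocount = 1, gap_penalty = -4,
                           params = align_params(), max_iter = 20L) {
  stopifnot(length(seed_seqs) >= 1)
  pool <- database_seqs[setdiff(names(database_seqs), names(seed_seqs))]
  seeds <- seed_seqs
  removed <- character(0)
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    profile <- build_profile(star_align(seeds, params), background, pseudocount,
                             gap_penalty)
    seed_scores <- vapply(seeds, function(s) score_sequence(profile, s), numeric(1))
    worst <- min(seed_scores)
    db_ids <- setdiff(names(pool), names(seeds))
    db_scores <- if (length(db_ids) > 0) {
      vapply(pool[db_ids], function(s) score_sequence(profile, s), numeric(1))
    } else numeric(0)
    recruits <- names(db_scores)[db_scores > worst]
    if (length(recruits) == 0 || n_iter >= max_iter) break
    worst_id <- names(seed_scores)[which.min(seed_scores)]
    pool[worst_id] <- seeds[worst_id]
    seeds <- c(seeds[setdiff(names(seeds), worst_id)], pool[recruits])
  }
  profile$seed_ids <- names(seeds)
  profile$n_iterations <- n_iter
  final_scores <- vapply(seeds, function(s) score_sequence(profile, s), numeric(1))
  profile$gathering_cutoff <- profile$trusted_cutoff <- min(final_scores)
  non_seed <- setdiff(names(pool), names(seeds))
  profile$noise_cutoff <- if (length(database_seqs) == 0) {
    NA_real_
  } else if (length(non_seed) == 0) {
    -Inf
  } else {
    max(vapply(pool[non_seed], function(s) score_sequence(profile, s), numeric(1)))
  }
  profile
}

#' Serialize a profile model to JSON
#' @param profile A `profile_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  obj <- list(columns = unname(apply(profile$columns, 2, as.list)),
              alphabet = rownames(profile$columns),
              background = as.list(profile$background),
              gap_penalty = profile$gap_penalty,
              seed_ids = profile$seed_ids,
              gathering_cutoff = profile$gathering_cutoff,
              trusted_cutoff = profile$trusted_cutoff,
              noise_cutoff = profile$noise_cutoff,
              n_iterations = profile$n_iterations)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
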