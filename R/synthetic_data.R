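#' @keywords internal
empty_truth <- function() {
  list(planted_loci = list(), decoys = character(0),
       ta_pairs = data.frame(antitoxin_protein_id = character(0),
                             toxin_protein_id = character(0),
                             antitoxin_upstream = logical(0),
                             antitoxin_strand = character(0),
                             toxin_strand = character(0),
                             stringsAsFactors = FALSE),
       family_memberships = setNames(character(0), character(0)),
       cohort_effects = NULL)
}

#' Generate a random amino-acid sequence
#'
#' @param len Length in residues.
#' @param freqs Background residue frequencies (default uniform over the 20
#'   standard residues).
#' @return A character scalar.
#' @export
random_protein <- function(len, freqs = NULL) {
  aa <- amino_acids()
  if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  paste(sample(aa, len, replace = TRUE, prob = freqs), collapse = "")
}

#' Simulate an annotated replicon
#'
#' Generates `n_genes` non-overlapping genes with lengths and intergenic gaps
#' drawn from gamma/Poisson distributions, random strands, and random
#' amino-acid sequences at the configured background frequencies. Fully
#' deterministic for a fixed seed.
#'
#' @param n_genes Number of genes (>= 1).
#' @param mean_gene_len Mean gene length in bp (default 900, i.e. ~300
#'   residues, a typical prokaryotic gene).
#' @param seed Integer seed.
#' @param replicon_id Replicon name.
#' @param aa_freqs Optional residue background frequencies.
#' @return A list of class `cas_sim` with `genes` (gene table), `proteins`
#'   (named character vector) and `truth` (ground-truth record).
#' @export
simulate_replicon <- function(n_genes, mean_gene_len = 900, seed = 1,
                              replicon_id = "rep1", aa_freqs = NULL) {
  if (!is.numeric(n_genes) || n_genes < 1) stop("n_genes must be >= 1")
  n_genes <- as.integer(n_genes)
  set.seed(derive_seed(seed, paste0("replicon:", replicon_id)))
  lens_bp <- 3L * pmax(50L, as.integer(round(
    rgamma(n_genes, shape = 9, scale = mean_gene_len / 3 / 9))))
  gaps <- 20L + as.integer(stats::rpois(n_genes, 100))
  starts <- cumsum(gaps + c(0L, lens_bp[-n_genes] - 1L) + 1L)
  ends <- starts + lens_bp - 1L
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  ids <- sprintf("%s_p%04d", replicon_id, seq_len(n_genes))
  proteins <- setNames(vapply(lens_bp %/% 3L, random_protein, character(1),
                              freqs = aa_freqs), ids)
  genes <- gene_table(data.frame(replicon_id = replicon_id, start = starts,
                                 end = ends, strand = strands, protein_id = ids,
                                 stringsAsFactors = FALSE))
  structure(list(genes = genes, proteins = proteins, truth = empty_truth()),
            class = "cas_sim")
}

#' Combine simulated replicons into one dataset
#' @param ... `cas_sim` objects with distinct replicon ids.
#' @return A single `cas_sim`.
#' @export
combine_sims <- function(...) {
  sims <- list(...)
  genes <- gene_table(do.call(rbind, lapply(sims, function(s)
    s$genes[, c("replicon_id", "start", "end", "strand", "protein_id", "product")])))
  proteins <- do.call(c, lapply(sims, function(s) s$proteins))
  truth <- empty_truth()
  truth$planted_loci <- do.call(c, lapply(sims, function(s) s$truth$planted_loci))
  truth$decoys <- do.call(c, lapply(sims, function(s) s$truth$decoys))
  truth$ta_pairs <- do.call(rbind, lapply(sims, function(s) s$truth$ta_pairs))
  truth$family_memberships <- do.call(c, lapply(sims, function(s)
    s$truth$family_memberships))
  structure(list(genes = genes, proteins = proteins, truth = truth),
            class = "cas_sim")
}

default_layouts <- function() {
  list(`I-A` = c("cas3", "cas8a1", "cas7", "cas5", "cas1", "cas2"),
       `I-B` = c("cas3", "cas8b", "cas7", "cas5", "cas1", "cas2"),
       `I-C` = c("cas3", "cas8c", "cas7", "cas5", "cas1", "cas2"),
       `IC-variant` = c("cas3", "GSU0054", "cas7", "cas5", "cas1", "cas2"),
       `I-D` = c("cas3", "cas10d", "cas7", "cas5", "cas1", "cas2"),
       `I-E` = c("cas3", "cse1", "cas7", "cas5", "cas1", "cas2"),
       `I-F` = c("cas3", "csy1", "cas7", "cas5", "cas1", "cas2"),
       `II-A` = c("cas9", "cas1", "cas2", "csn2"),
       `II-B` = c("cas9", "cas1", "cas2", "cas4"),
       `II-C` = c("cas9", "cas1", "cas2"),
       `III-A` = c("cas10", "csm2", "cas7", "cas1", "cas2"),
       `III-B` = c("cas10", "cmr", "cas7", "cas1", "cas2"))
}

#' Plant a cas locus of a known subtype into a simulated replicon
#'
#' Assigns consecutive genes the families of `layout`, records the planted
#' subtype in the ground truth, and marks each member's hit role: `seed`
#' members will receive a strong (gathering-cutoff) hit from
#' [emit_hit_table()], `recruit` members a weak hit (`1e-6 <= E <= 1e-3`).
#' Optionally inserts an unannotated gene mid-locus (a future novel-family
#' candidate) and/or accessory genes carrying non-Cas annotations (toxin,
#' antitoxin, transposase families).
#'
#' @param sim A `cas_sim`.
#' @param subtype Subtype label present in the signature map.
#' @param layout Ordered character vector of family ids; default is the
#'   subtype's standard layout, which includes its signature family.
#' @param at 0-based `gene_index` at which the locus starts; default picks a
#'   random free position.
#' @param seed Integer seed (used only when `at` is `NULL` or strand draws
#'   are needed).
#' @param roles Optional `"seed"`/`"recruit"` vector matching `layout`;
#'   default makes cas1/cas3/cas9/cas10 seeds and the rest recruits.
#' @param insert_unknown Insert one unannotated gene mid-locus.
#' @param accessory Character vector of non-Cas family ids inserted as
#'   adjacent genes mid-locus (e.g. `c("PhdYeFM_antitox", "PIN")`).
#' @param accessory_strand `"same"` or `"opposite"` relative to the locus
#'   strand, recycled over accessories; default `"same"`.
#' @param sigmap A [load_signature_map()] object.
#' @param ta A [load_ta_families()] configuration (to recognize planted
#'   toxin/antitoxin pairs for the ground truth).
#' @return The updated `cas_sim`.
#' @export
plant_cas_locus <- function(sim, subtype, layout = NULL, at = NULL, seed = 1,
                            roles = NULL, insert_unknown = FALSE,
                            accessory = NULL, accessory_strand = "same",
                            sigmap = load_signature_map(), ta = load_ta_families()) {
  if (!subtype %in% sigmap$subtypes) stop("unknown subtype: ", subtype)
  if (is.null(layout)) layout <- default_layouts()[[subtype]]
  sig_fams <- names(Filter(function(f) identical(f$subtype, subtype), sigmap$families))
  if (subtype != "II-C" && !any(sig_fams %in% layout)) {
    stop("layout lacks the signature family of subtype ", subtype)
  }
  if (is.null(roles)) {
    roles <- ifelse(layout %in% c("cas1", "cas3", "cas9", "cas10"), "seed", "recruit")
    if (!any(roles == "seed")) roles[1] <- "seed"
  }
  stopifnot(length(roles) == length(layout), all(roles %in% c("seed", "recruit")))

  # interleave optional unknown / accessory genes at interior positions
  fams <- layout
  memb_roles <- roles
  mid <- max(2L, ceiling(length(layout) / 2))
  if (insert_unknown) {
    fams <- append(fams, NA_character_, after = mid - 1L)
    memb_roles <- append(memb_roles, "unknown", after = mid - 1L)
  }
  if (!is.null(accessory)) {
    pos <- min(length(fams) - 1L, mid)  # keep boundary members labeled
    fams <- append(fams, accessory, after = pos)
    memb_roles <- append(memb_roles, rep("accessory", length(accessory)), after = pos)
  }
  n_need <- length(fams)

  g <- sim$genes
  rep_ids <- unique(g$replicon_id)
  if (length(rep_ids) != 1) stop("plant_cas_locus expects a single-replicon sim; use before combine_sims")
  n <- nrow(g)
  taken <- rep(FALSE, n)
  for (pl in sim$truth$planted_loci) {
    taken[g$gene_index >= pl$first_index & g$gene_index <= pl$last_index] <- TRUE
  }
  set.seed(derive_seed(seed, paste0("plant:", subtype, ":", length(sim$truth$planted_loci))))
  if (is.null(at)) {
    # leave one free gene between planted loci so chains cannot merge
    free_start <- which(vapply(seq_len(n - n_need + 1L), function(i)
      !any(taken[max(1L, i - 4L):min(n, i + n_need + 3L)]), logical(1)))
    if (length(free_start) == 0) stop("layout longer than remaining replicon")
    at <- g$gene_index[free_start[sample.int(length(free_start), 1)]]
  }
  rows <- which(g$gene_index >= at & g$gene_index < at + n_need)
  if (length(rows) < n_need) stop("layout longer than remaining replicon")

  locus_strand <- sample(c("+", "-"), 1)
  sim$genes$strand[rows] <- locus_strand
  acc_strand <- rep_len(accessory_strand, max(1L, length(accessory)))
  acc_i <- 0L
  for (k in seq_along(rows)) {
    if (memb_roles[k] == "accessory") {
      acc_i <- acc_i + 1L
      if (acc_strand[acc_i] == "opposite") {
        sim$genes$strand[rows[k]] <- if (locus_strand == "+") "-" else "+"
      }
    }
  }

  ids <- sim$genes$protein_id[rows]
  members <- data.frame(protein_id = ids,
                        gene_index = sim$genes$gene_index[rows],
                        family = fams, role = memb_roles,
                        stringsAsFactors = FALSE)
  known <- !is.na(fams)
  sim$truth$family_memberships[ids[known]] <- fams[known]
  sim$truth$planted_loci[[length(sim$truth$planted_loci) + 1L]] <- list(
    replicon_id = rep_ids, first_index = at, last_index = at + n_need - 1L,
    subtype = subtype, members = members)

  # record any adjacent (antitoxin, toxin) accessory pair in the truth
  if (!is.null(accessory)) {
    acc_rows <- which(members$role == "accessory")
    for (i in acc_rows) {
      for (j in acc_rows) {
        if (members$family[i] %in% ta$antitoxins && members$family[j] %in% ta$toxins &&
            abs(members$gene_index[i] - members$gene_index[j]) <= 2) {
          upstream <- if (locus_strand == "+") {
            members$gene_index[i] < members$gene_index[j]
          } else members$gene_index[i] > members$gene_index[j]
          sim$truth$ta_pairs <- rbind(sim$truth$ta_pairs, data.frame(
            antitoxin_protein_id = members$protein_id[i],
            toxin_protein_id = members$protein_id[j],
            antitoxin_upstream = upstream,
            antitoxin_strand = sim$genes$strand[rows[i]],
            toxin_strand = sim$genes$strand[rows[j]],
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  sim
}

#' Mutate a sequence to a target global identity
#'
#' Applies point substitutions (no indels) at random positions so that the
#' realized identity to the input is within two percentage points of the
#' target, as verified by the package's own aligner.
#'
#' @param seq Amino-acid sequence of length >= 20.
#' @param target_identity Fraction in (0, 1].
#' @param seed Integer seed.
#' @return The mutated sequence.
#' @export
mutate_to_identity <- function(seq, target_identity, seed = 1) {
  stopifnot(target_identity > 0, target_identity <= 1)
  if (target_identity == 1) return(seq)
  L <- nchar(seq)
  if (L < 20) stop("target identity unreachable on sequences shorter than 20 residues")
  set.seed(derive_seed(seed, "mutate"))
  k <- round((1 - target_identity) * L)
  if (k == 0) return(seq)
  pos <- sample(L, k)
  chars <- strsplit(seq, "")[[1]]
  aa <- amino_acids()
  for (p in pos) chars[p] <- sample(setdiff(aa, chars[p]), 1)
  paste(chars, collapse = "")
}

#' Generate a synthetic protein family
#'
#' Members are independent mutants of one random ancestor, each at
#' `ancestor_identity` to it; pairwise member identity is correspondingly
#' lower (roughly `1 - 2(1 - ancestor_identity)` plus chance agreement).
#'
#' @param n_members Number of members.
#' @param len Member length in residues.
#' @param ancestor_identity Identity of each member to the common ancestor;
#'   recycled over members, so divergence may vary within the family.
#' @param seed Integer seed.
#' @param prefix Id prefix.
#' @return Named character vector of sequences; the ancestor is attached as
#'   attribute `"ancestor"`.
#' @export
synth_family <- function(n_members, len = 150, ancestor_identity = 0.85,
                         seed = 1, prefix = "fam") {
  set.seed(derive_seed(seed, paste0("family:", prefix)))
  anc <- random_protein(len)
  ident <- rep_len(ancestor_identity, n_members)
  seeds <- sample.int(1e8, n_members)
  seqs <- vapply(seq_len(n_members), function(i)
    mutate_to_identity(anc, ident[i], seed = seeds[i]), character(1))
  structure(setNames(seqs, sprintf("%s_m%02d", prefix, seq_len(n_members))),
            ancestor = anc)
}

#' Generate the profile-refinement study fixture
#'
#' One synthetic family split into a seed set and held-out true members,
#' plus unrelated decoys, emulating a family whose database relatives
#' include close homologs of the consensus. Seeds sit at `seed_identity` to
#' the family ancestor; held-out members at `heldout_identity` (closer, as
#' database homologs of a well-sampled family typically are); decoys are
#' random background sequences.
#'
#' @param n_seeds,n_heldout,n_decoys Set sizes (defaults 5 / 3 / 50).
#' @param len Sequence length in residues.
#' @param seed_identity,heldout_identity Ancestor identity of the two tiers
#'   (defaults 0.85 and 0.98).
#' @param seed Integer seed.
#' @return List with `seeds`, `held_out`, `decoys` (named character
#'   vectors) and `database` (`held_out` + `decoys`).
#' @export
synth_refinement_family <- function(n_seeds = 5, n_heldout = 3, n_decoys = 50,
                                    len = 120, seed_identity = 0.85,
                                    heldout_identity = 0.98, seed = 1) {
  fam <- synth_family(n_seeds + n_heldout, len = len,
                      ancestor_identity = c(rep(seed_identity, n_seeds),
                                            rep(heldout_identity, n_heldout)),
                      seed = seed, prefix = "fam")
  set.seed(derive_seed(seed, "refinement-decoys"))
  decoys <- setNames(vapply(seq_len(n_decoys), function(i) random_protein(len),
                            character(1)),
                     sprintf("decoy%02d", seq_len(n_decoys)))
  seeds_set <- fam[seq_len(n_seeds)]
  held <- fam[n_seeds + seq_len(n_heldout)]
  names(held) <- sub("^fam", "held", names(held))
  list(seeds = seeds_set, held_out = held, decoys = decoys,
       database = c(held, decoys))
}

#' Emit a hit table for a simulated dataset
#'
#' Seed-role members receive strong hits (`meets_gathering = TRUE`,
#' `E` in `[1e-30, 1e-10]`); recruit-role members receive weak hits
#' (`1e-6 <= E <= 1e-3`); and each non-planted gene receives a spurious weak
#' decoy hit (`E` in `(1e-3, 10]`, below no threshold) with probability
#' `fp_rate`. With `scope = "all"` the table additionally carries the
#' accessory genes' non-Cas annotations, emulating a search against the full
#' family database rather than Cas families only.
#'
#' @param sim A `cas_sim` (after planting).
#' @param fp_rate Spurious-hit probability per non-planted gene, in `[0, 1)`.
#' @param seed Integer seed.
#' @param scope `"cas"` (Cas families only) or `"all"` (full database,
#'   including accessory annotations).
#' @return A best-hit-reduced hit table; the ids of genes that drew a decoy
#'   hit are attached as attribute `"decoy_ids"`.
#' @export
emit_hit_table <- function(sim, fp_rate = 0, seed = 1, scope = c("cas", "all")) {
  scope <- match.arg(scope)
  stopifnot(fp_rate >= 0, fp_rate < 1)
  set.seed(derive_seed(seed, paste0("hits:", scope)))
  rows <- list()
  for (pl in sim$truth$planted_loci) {
    m <- pl$members
    for (i in seq_len(nrow(m))) {
      if (m$role[i] == "seed") {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = m$protein_id[i], family_id = m$family[i],
          bit_score = runif(1, 150, 500), e_value = 10^runif(1, -30, -10),
          meets_gathering = TRUE, stringsAsFactors = FALSE)
      } else if (m$role[i] == "recruit") {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = m$protein_id[i], family_id = m$family[i],
          bit_score = runif(1, 25, 55), e_value = 10^runif(1, -6, -3),
          meets_gathering = FALSE, stringsAsFactors = FALSE)
      } else if (m$role[i] == "accessory" && scope == "all") {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = m$protein_id[i], family_id = m$family[i],
          bit_score = runif(1, 80, 200), e_value = 10^runif(1, -25, -10),
          meets_gathering = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  planted_ids <- unlist(lapply(sim$truth$planted_loci, function(pl)
    pl$members$protein_id), use.names = FALSE)
  decoy_pool <- setdiff(sim$genes$protein_id, planted_ids)
  hit_decoy <- decoy_pool[runif(length(decoy_pool)) < fp_rate]
  cas_fams <- names(load_signature_map()$families)
  for (id in hit_decoy) {
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = id, family_id = sample(cas_fams, 1),
      bit_score = runif(1, 10, 25), e_value = 10^runif(1, -2.9, 1),
      meets_gathering = FALSE, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) hit_table(do.call(rbind, rows)) else empty_hits()
  attr(out, "decoy_ids") <- hit_decoy
  out
}

#' Simulate a multi-habitat cohort of gene inventories
#'
#' For each subject and habitat, the subject-level cas fraction is the
#' habitat mean scaled by mean-one log-normal noise (`dispersion` on the log
#' scale), the total gene count is drawn uniformly from `total_range`, and
#' the cas count is binomial. Emulates a cohort of subjects sampled at stool
#' and sub-oral sites.
#'
#' @param n_subjects Number of subjects (default 65).
#' @param habitat_means Named vector of mean cas-gene fractions per habitat,
#'   each in `[0, 1)`.
#' @param dispersion Log-scale SD of the subject effect (default 0.3).
#' @param seed Integer seed.
#' @param total_range Range of total gene counts per sample.
#' @return Data frame `subject_id`, `habitat`, `n_total_genes`, `n_cas_genes`.
#' @export
simulate_cohort <- function(n_subjects = 65,
                            habitat_means = c(stool = 0.002, buccal_mucosa = 0.003,
                                              supragingival_plaque = 0.005,
                                              tongue_dorsum = 0.006),
                            dispersion = 0.3, seed = 1,
                            total_range = c(20000, 60000)) {
  if (any(habitat_means < 0 | habitat_means >= 1)) {
    stop("habitat means must be fractions in [0, 1)")
  }
  set.seed(derive_seed(seed, "cohort"))
  out <- expand.grid(subject_id = sprintf("S%03d", seq_len(n_subjects)),
                     habitat = names(habitat_means),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$habitat), , drop = FALSE]
  frac <- habitat_means[out$habitat] *
    exp(rnorm(nrow(out), 0, dispersion) - dispersion^2 / 2)
  frac <- pmin(frac, 0.999)
  out$n_total_genes <- as.integer(round(runif(nrow(out), total_range[1], total_range[2])))
  out$n_cas_genes <- rbinom(nrow(out), out$n_total_genes, frac)
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset to standard files
#'
#' @param sim A `cas_sim`.
#' @param dir Output directory (created if needed); writes `genes.gff3`,
#'   `genes.tsv`, `proteins.faa`, `hits.tsv`, `all_hits.tsv`, `truth.json`.
#' @param fp_rate,seed Passed to [emit_hit_table()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, fp_rate = 0, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_table(sim$genes, file.path(dir, "genes.tsv"), "tsv")
  write_gene_table(sim$genes, file.path(dir, "genes.gff3"), "gff3")
  write_fasta(sim$proteins, file.path(dir, "proteins.faa"))
  write_hit_table(emit_hit_table(sim, fp_rate, seed, "cas"), file.path(dir, "hits.tsv"))
  write_hit_table(emit_hit_table(sim, fp_rate, seed, "all"), file.path(dir, "all_hits.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
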