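test_that("pairwise alignment matches an affine-gap dynamic-programming oracle", {
  s <- "MKLVWYACDE"
  self <- align_pair(s, s)
  expect_equal(self$identity, 1.0)

  set.seed(5)
  for (k in 1:5) {
    a <- random_protein(10)
    b <- random_protein(sample(8:12, 1))
    ab <- align_pair(a, b)
    ba <- align_pair(b, a)
    expect_equal(ab$raw_score, ba$raw_score)
    expect_equal(ab$identity, ba$identity)
    expect_equal(ab$raw_score, oracle_gotoh(a, b))
  }
  expect_error(align_pair("", "MK"), "empty")

  # bit score is the Karlin-Altschul transform of the raw score
  p <- align_params()
  expect_equal(align_pair(s, s)$bit_score,
               (p$lambda * align_pair(s, s)$raw_score - log(p$K)) / log(2))
})

test_that("greedy redundancy reduction honors the identity threshold", {
  base <- random_protein_fixture(100, 21)
  dup <- c(a = base, b = base)
  r <- reduce_redundancy(dup)
  expect_length(r$representatives, 1)

  # three mutually ~95%-identical sequences collapse onto the longest
  long <- paste0(base, random_protein_fixture(6, 22))
  s2 <- mutate_to_identity(base, 0.95, seed = 1)
  s3 <- mutate_to_identity(base, 0.95, seed = 2)
  r3 <- reduce_redundancy(c(x = s2, longest = long, y = s3))
  expect_equal(r3$representatives, "longest")
  expect_setequal(names(r3$membership), c("x", "longest", "y"))

  # 50% identity: both stay
  r50 <- reduce_redundancy(c(a = base, b = mutate_to_identity(base, 0.5, seed = 3)))
  expect_length(r50$representatives, 2)

  # invariants on a mixed synthetic set: removed sequences are >= 90% to
  # their representative; representatives are mutually < 90%
  seqs <- c(synth_family(4, len = 120, ancestor_identity = 0.95, seed = 31, prefix = "ra"),
            synth_family(3, len = 110, ancestor_identity = 0.6, seed = 32, prefix = "rb"))
  rr <- reduce_redundancy(seqs)
  for (id in names(rr$membership)) {
    rep_id <- rr$membership[[id]]
    if (id != rep_id) {
      expect_gte(pairwise_identity(seqs[[id]], seqs[[rep_id]]), 0.90)
    }
  }
  reps <- rr$representatives
  if (length(reps) > 1) {
    for (i in seq_len(length(reps) - 1)) {
      for (j in seq(i + 1, length(reps))) {
        expect_lt(pairwise_identity(seqs[[reps[i]]], seqs[[reps[j]]]), 0.90)
      }
    }
  }
  # determinism
  expect_identical(reduce_redundancy(seqs)$representatives, reps)
})

test_that("similarity graphs connect related proteins and not random ones", {
  single <- build_graph(c(only = random_protein_fixture(150, 41)))
  expect_equal(single$nodes, "only")
  expect_equal(nrow(single$edges), 0)

  fam <- synth_family(6, len = 150, ancestor_identity = 0.8, seed = 42, prefix = "cl")
  g <- build_graph(fam)
  expect_equal(nrow(g$edges), choose(6, 2))  # a 6-clique
  expect_true(all(g$edges$weight > 60))

  for (s in 43:44) {
    set.seed(s)
    rnd <- setNames(vapply(1:4, function(i) random_protein(150), character(1)),
                    paste0("r", 1:4))
    expect_equal(nrow(build_graph(rnd)$edges), 0)
  }
})

test_that("markov clustering splits components and weakly bridged cliques", {
  expect_equal(mcl(structure(list(nodes = character(0),
                                  edges = data.frame(from = character(0),
                                                     to = character(0),
                                                     weight = numeric(0))),
                             class = "similarity_graph")), list())

  one <- clique_graph(1)
  expect_equal(mcl(one), list("k1_n1"))

  two4 <- clique_graph(c(4, 4))
  cl <- mcl(two4)
  expect_length(cl, 2)
  expect_setequal(unlist(cl), two4$nodes)

  # two 5-cliques joined by an edge at a tenth of the clique weight
  bridged <- clique_graph(c(5, 5), w = 100,
                          bridges = list(list("k1_n1", "k2_n1", 10)))
  clb <- mcl(bridged, inflation = 1.4)
  expect_length(clb, 2)
  expect_identical(canonical_partition(clb),
                   canonical_partition(list(paste0("k1_n", 1:5),
                                            paste0("k2_n", 1:5))))

  # every node lands in exactly one cluster; relabeling does not matter
  g <- random_graph(7)
  part <- mcl(g)
  expect_setequal(unlist(part), g$nodes)
  expect_equal(length(unlist(part)), length(g$nodes))
})

test_that("family selection enforces size and flags diversity", {
  fam_tight <- synth_family(6, len = 120, ancestor_identity = 0.85, seed = 51, prefix = "t")
  fam_loose <- synth_family(6, len = 120, ancestor_identity = 0.62, seed = 52, prefix = "l")
  small <- synth_family(4, len = 120, ancestor_identity = 0.85, seed = 53, prefix = "s")
  seqs <- c(fam_tight, fam_loose, small,
            c(solo = random_protein_fixture(120, 54)))
  clusters <- list(names(fam_tight), names(fam_loose), names(small), "solo")
  res <- select_novel_families(clusters, seqs)
  expect_length(res$families, 2)
  expect_equal(nrow(res$discards), 5)  # the 4-member cluster and the singleton
  tight <- res$families[[1]]
  loose <- res$families[[2]]
  expect_false(tight$passed_diversity)   # ~70% pairwise identity
  expect_true(loose$passed_diversity)    # diverged below 50%
  expect_lte(loose$max_pairwise_identity, 0.5)
})

test_that("known-likeness exclusion requires E-value AND identity jointly", {
  ref <- c(cas2_ref = random_protein_fixture(120, 61))
  member_close <- mutate_to_identity(ref[[1]], 0.8, seed = 62)

  # conservative substitutions: high raw score, low identity
  partner <- c(D = "E", E = "D", K = "R", R = "K", I = "V", V = "I",
               F = "Y", Y = "F", L = "M", M = "L", Q = "E", T = "S",
               S = "T", W = "Y", A = "S")
  set.seed(63)
  base_chars <- sample(names(partner), 160, replace = TRUE)
  swap <- runif(160) < 0.75
  cons_chars <- ifelse(swap, partner[base_chars], base_chars)
  base <- paste(base_chars, collapse = "")
  cons <- paste(cons_chars, collapse = "")
  sc <- align_pair(cons, base)
  ev <- alignment_evalue(sc$raw_score, 160, 160)
  expect_lt(ev, 1e-5)          # strong similarity ...
  expect_lt(sc$identity, 0.30) # ... but below the identity bound

  fams <- list(list(family_id = "f1", members = "m1", passed_size = TRUE,
                    passed_diversity = TRUE, excluded_known_like = NA),
               list(family_id = "f2", members = "m2", passed_size = TRUE,
                    passed_diversity = TRUE, excluded_known_like = NA),
               list(family_id = "f3", members = "m3", passed_size = TRUE,
                    passed_diversity = TRUE, excluded_known_like = NA))
  seqs <- c(m1 = member_close, m2 = cons, m3 = random_protein_fixture(120, 64))
  out <- exclude_known_like(fams, c(ref, base_ref = base), seqs)
  expect_true(out[[1]]$excluded_known_like)   # 80% identity, tiny E
  expect_false(out[[2]]$excluded_known_like)  # identity below 30%
  expect_false(out[[3]]$excluded_known_like)  # no similarity at all

  expect_warning(out2 <- exclude_known_like(fams, character(0), seqs), "empty")
  expect_false(any(vapply(out2, function(f) f$excluded_known_like, logical(1))))
})
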