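test_that("seed finding equals a plain filter on the gathering flag", {
  expect_equal(find_seeds(hit_table(make_hit("p1")[0, ])), character(0))

  h <- rbind(make_hit("p1", ga = TRUE), make_hit("p2", "cas7", 30, 1e-4, ga = FALSE))
  expect_equal(find_seeds(hit_table(h)), "p1")

  set.seed(1)
  h20 <- do.call(rbind, lapply(1:20, function(i)
    make_hit(paste0("q", i), family = sample(c("cas1", "cas2"), 1),
             ga = runif(1) < 0.4)))
  h20 <- hit_table(h20)
  expect_setequal(find_seeds(h20), unique(h20$protein_id[h20$meets_gathering]))
})

test_that("recruitment chains through recruited genes but respects the window", {
  genes <- make_genes(0:20)
  hits <- hit_table(rbind(
    make_hit("p5", ga = TRUE),
    make_hit("p8", "cas7", 30, 1e-4, ga = FALSE),
    make_hit("p11", "cas7", 30, 1e-4, ga = FALSE),
    make_hit("p15", "cas7", 30, 1e-4, ga = FALSE)))
  labels <- recruit_iteratively(genes, hits, "p5")
  # 8 within 3 of the seed; 11 within 3 of recruited 8; 15 is 4 from 11
  expect_equal(labels[["p5"]], "SEED_KNOWN")
  expect_equal(labels[["p8"]], "RECRUITED_KNOWN")
  expect_equal(labels[["p11"]], "RECRUITED_KNOWN")
  expect_false("p15" %in% names(labels))

  # isolated weak-hit gene: nothing within the window to pull it in
  hits2 <- hit_table(rbind(make_hit("p0", ga = TRUE),
                           make_hit("p9", "cas7", 30, 1e-4, ga = FALSE)))
  labels2 <- recruit_iteratively(genes, hits2, "p0")
  expect_equal(names(labels2), "p0")

  # no weak hits at all: output is exactly the seeds
  labels3 <- recruit_iteratively(genes, hit_table(make_hit("p3")), "p3")
  expect_equal(names(labels3), "p3")

  expect_error(recruit_iteratively(genes, hits, "absent"), "absent")
})

test_that("recruitment is a fixed point and independent of row order", {
  for (s in c(101, 202, 303)) {
    case <- random_recruitment_case(s)
    labels <- recruit_iteratively(case$genes, case$hits, case$seeds)
    # fixed point: feeding the labeled set back as seeds adds nothing
    again <- recruit_iteratively(case$genes, case$hits, names(labels))
    expect_setequal(names(again), names(labels))
    # row order of the gene table is irrelevant
    set.seed(s)
    shuffled <- case$genes[sample(nrow(case$genes)), ]
    shuffled <- gene_table(shuffled[, c("replicon_id", "start", "end",
                                        "strand", "protein_id", "product")])
    labels2 <- recruit_iteratively(shuffled, case$hits, case$seeds)
    expect_identical(labels2[sort(names(labels2))], labels[sort(names(labels))])
  }
})

test_that("locus assembly fills spans, breaks chains, and requires a seed", {
  genes <- make_genes(0:12)

  lab <- setNames(c("SEED_KNOWN", "RECRUITED_KNOWN", "RECRUITED_KNOWN"),
                  c("p2", "p3", "p4"))
  loci <- assemble_loci(genes, lab)
  expect_length(loci, 1)
  expect_equal(c(loci[[1]]$first_index, loci[[1]]$last_index), c(2, 4))
  expect_false("INTERVENING_UNKNOWN" %in% loci[[1]]$members$label)

  # gap of 3 within the window: interior unlabeled genes become intervening
  lab2 <- setNames(c("SEED_KNOWN", "RECRUITED_KNOWN"), c("p2", "p5"))
  loci2 <- assemble_loci(genes, lab2)
  expect_length(loci2, 1)
  m <- loci2[[1]]$members
  expect_equal(m$label[m$protein_id %in% c("p3", "p4")],
               rep("INTERVENING_UNKNOWN", 2))
  # boundary members are never intervening
  expect_false(m$label[1] == "INTERVENING_UNKNOWN")
  expect_false(m$label[nrow(m)] == "INTERVENING_UNKNOWN")

  # gap of 7 > window: two separate loci
  lab3 <- setNames(c("SEED_KNOWN", "SEED_KNOWN"), c("p2", "p9"))
  expect_length(assemble_loci(genes, lab3), 2)

  # chains never cross replicon boundaries
  two <- rbind(make_genes(0:5, "repA"), make_genes(0:5, "repB"))
  two$protein_id <- paste0(two$replicon_id, "_", two$protein_id)
  two <- gene_table(two[, c("replicon_id", "start", "end", "strand",
                            "protein_id", "product")])
  lab4 <- setNames(c("SEED_KNOWN", "SEED_KNOWN"), c("repA_p5", "repB_p0"))
  expect_length(assemble_loci(two, lab4), 2)

  # a recruited-only chain (no seed) is discarded
  lab5 <- setNames(c("RECRUITED_KNOWN", "RECRUITED_KNOWN"), c("p2", "p3"))
  expect_length(assemble_loci(genes, lab5), 0)
})

test_that("novel candidates are intervening genes with no annotation of any kind", {
  members <- data.frame(protein_id = c("p2", "p3", "p4", "p5"),
                        gene_index = 2:5,
                        label = c("SEED_KNOWN", "INTERVENING_UNKNOWN",
                                  "INTERVENING_UNKNOWN", "RECRUITED_KNOWN"),
                        stringsAsFactors = FALSE)
  locus <- make_locus(members)
  all_hits <- hit_table(make_hit("p3", "Transposase_20", 80, 1e-15, TRUE))
  res <- collect_novel_candidates(list(locus), all_hits)
  expect_equal(res$candidates, "p4")
  expect_equal(res$assorted$protein_id, "p3")
  expect_equal(res$assorted$family_id, "Transposase_20")

  # a locus without intervening members contributes nothing
  m2 <- members[c(1, 4), ]
  expect_length(collect_novel_candidates(list(make_locus(m2)), all_hits)$candidates, 0)
})
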