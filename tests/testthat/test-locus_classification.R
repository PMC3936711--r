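sigmap <- load_signature_map()

call_for <- function(families, completeness = "DRAFT_OR_CONTIG") {
  n <- length(families)
  members <- data.frame(protein_id = paste0("m", seq_len(n)),
                        gene_index = seq_len(n) - 1L,
                        label = "SEED_KNOWN", stringsAsFactors = FALSE)
  locus <- make_locus(members, completeness = completeness)
  ann <- setNames(families, members$protein_id)
  assign_types(locus, ann, sigmap)
}

test_that("signature genes resolve subtypes, with composition-defined II-C", {
  expect_equal(call_for(c("cas9", "cas1", "cas2", "csn2"))$subtypes, "II-A")
  expect_equal(call_for(c("cas9", "cas1", "cas2", "cas4"))$subtypes, "II-B")

  cc <- call_for(c("cas9", "cas1", "cas2"), "COMPLETE_GENOME")
  expect_equal(cc$subtypes, "II-C")
  expect_equal(cc$types, "II")

  # the same composition on a draft/contig: type II but no subtype
  dr <- call_for(c("cas9", "cas1", "cas2"), "DRAFT_OR_CONTIG")
  expect_equal(dr$types, "II")
  expect_length(dr$subtypes, 0)

  # type signature without a subtype signature still calls the type
  t1 <- call_for(c("cas3", "cas7", "cas5"))
  expect_equal(t1$types, "I")
  expect_length(t1$subtypes, 0)

  # cas4 without cas9 is not type II evidence
  expect_length(call_for(c("cas3", "cas4", "cas7"))$subtypes, 0)

  # subtype always implies its parent type
  for (fams in list(c("cas9", "csn2"), c("cas3", "csy1"), c("cas10", "cmr"),
                    c("cas3", "GSU0054"))) {
    cl <- call_for(fams)
    for (s in cl$subtypes) {
      expect_true(sub("-.*", "", sub("^IC.*", "I", s)) %in% cl$types)
    }
  }

  expect_warning(call_for(c("cas9", "mystery_fam")), "unknown family")
})

test_that("cas9 co-located with other types' signatures raises flags", {
  cl <- detect_cooccurrence(call_for(c("cas9", "cas10", "cmr", "cas1")), sigmap)
  expect_true("II+III-B" %in% cl$cooccurrence_flags)
  expect_true("II+III" %in% cl$cooccurrence_flags)

  expect_length(detect_cooccurrence(call_for(c("cas9", "cas1", "cas2", "csn2")),
                                    sigmap)$cooccurrence_flags, 0)

  cl2 <- detect_cooccurrence(call_for(c("cas9", "csy1", "cas3")), sigmap)
  expect_true("II+I-F" %in% cl2$cooccurrence_flags)
  expect_true("I+II" %in% cl2$cooccurrence_flags)
})

test_that("adjacent antitoxin/toxin members pair up with orientation calls", {
  genes <- make_genes(0:6, strands = c("+", "+", "+", "+", "+", "+", "+"))
  members <- data.frame(protein_id = paste0("p", 0:5), gene_index = 0:5,
                        label = c("SEED_KNOWN", "RECRUITED_KNOWN",
                                  "INTERVENING_UNKNOWN", "INTERVENING_UNKNOWN",
                                  "RECRUITED_KNOWN", "SEED_KNOWN"),
                        stringsAsFactors = FALSE)
  locus <- make_locus(members)
  ann <- c(p0 = "cas3", p1 = "cas7", p2 = "PhdYeFM_antitox", p3 = "PIN",
           p4 = "cas5", p5 = "cas1")
  ta <- detect_toxin_antitoxin(locus, genes, ann)
  expect_equal(nrow(ta), 1)
  expect_true(ta$antitoxin_upstream)   # cas genes on +, antitoxin at lower index
  expect_true(ta$antitoxin_same_strand && ta$toxin_same_strand)

  # on the minus strand the same gene order means the antitoxin is downstream
  genes_m <- make_genes(0:6, strands = "-")
  ta_m <- detect_toxin_antitoxin(locus, genes_m, ann)
  expect_false(ta_m$antitoxin_upstream)

  # toxin alone pairs with nothing
  ann2 <- ann
  ann2["p2"] <- "cas6"
  expect_equal(nrow(detect_toxin_antitoxin(locus, genes, ann2)), 0)

  # members three genes apart are not a pair
  members3 <- members
  members3$gene_index <- c(0L, 1L, 2L, 5L, 6L, 7L)
  members3$protein_id <- paste0("p", members3$gene_index)
  genes8 <- make_genes(0:8)
  ann3 <- c(p0 = "cas3", p1 = "cas7", p2 = "PhdYeFM_antitox", p5 = "PIN",
            p6 = "cas5", p7 = "cas1")
  expect_equal(nrow(detect_toxin_antitoxin(make_locus(members3), genes8, ann3)), 0)

  # a strand tie among cas genes leaves orientation indeterminate
  genes_tie <- make_genes(0:6, strands = c("+", "-", "+", "-", "+", "-", "+"))
  members_tie <- members[c(1, 2, 3, 4, 5, 6), ]
  ta_tie <- detect_toxin_antitoxin(make_locus(members_tie), genes_tie, ann)
  expect_true(is.na(ta_tie$antitoxin_upstream))
})

test_that("strand opposition matches hand counts and a fair-coin simulation", {
  # 13 single-transposase loci, 9 of them on the opposite strand: 69%
  loci <- list()
  genes_rows <- list()
  ann <- character(0)
  for (i in 1:13) {
    rep_id <- sprintf("r%02d", i)
    opp <- i <= 9
    strands <- c("+", "+", if (opp) "-" else "+", "+")
    g <- make_genes(0:3, replicon = rep_id, strands = strands)
    g$protein_id <- paste0(rep_id, "_", g$protein_id)
    genes_rows[[i]] <- g
    members <- data.frame(protein_id = g$protein_id, gene_index = 0:3,
                          label = c("SEED_KNOWN", "RECRUITED_KNOWN",
                                    "INTERVENING_UNKNOWN", "SEED_KNOWN"),
                          stringsAsFactors = FALSE)
    loci[[i]] <- make_locus(members, locus_id = paste0("L", i), replicon = rep_id)
    ann[g$protein_id] <- c("cas3", "cas7", "Transposase_20", "cas1")
  }
  genes <- do.call(rbind, genes_rows)
  res <- strand_opposition_fraction(loci, genes, ann, "Transposase_20")
  expect_equal(res$n_opposite, 9)
  expect_equal(res$n_total, 13)
  expect_equal(res$percent, 69)

  # all members on the cas strand: 0%
  genes$strand <- "+"
  res0 <- strand_opposition_fraction(loci, genes, ann, "Transposase_20")
  expect_equal(res0$fraction, 0)

  expect_error(strand_opposition_fraction(loci, genes, ann, "nope"), "no locus member")

  # random insertion strands over 1000 members land near one half
  set.seed(77)
  big_loci <- list()
  big_rows <- list()
  big_ann <- character(0)
  for (i in 1:1000) {
    rep_id <- sprintf("b%04d", i)
    strands <- c("+", "+", sample(c("+", "-"), 1), "+")
    g <- make_genes(0:3, replicon = rep_id, strands = strands)
    g$protein_id <- paste0(rep_id, "_", g$protein_id)
    big_rows[[i]] <- g
    members <- data.frame(protein_id = g$protein_id, gene_index = 0:3,
                          label = c("SEED_KNOWN", "RECRUITED_KNOWN",
                                    "INTERVENING_UNKNOWN", "SEED_KNOWN"),
                          stringsAsFactors = FALSE)
    big_loci[[i]] <- make_locus(members, locus_id = paste0("B", i), replicon = rep_id)
    big_ann[g$protein_id] <- c("cas3", "cas7", "Transposase_20", "cas1")
  }
  big_genes <- do.call(rbind, big_rows)
  frac <- strand_opposition_fraction(big_loci, big_genes, big_ann,
                                     "Transposase_20")$fraction
  expect_true(abs(frac - 0.5) < 0.05)
})
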