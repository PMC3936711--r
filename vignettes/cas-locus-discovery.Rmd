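---
title: "Discovering cas loci by similarity seeding and neighborhood recruitment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cas loci by similarity seeding and neighborhood recruitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casforge)
```

## The problem

*cas* genes encode the protein machinery of CRISPR–Cas adaptive immunity.
They occur in clusters (loci) beside CRISPR arrays, but many Cas families
evolve quickly, so a similarity search alone misses genuine *cas* genes
whose best hit falls below a trustworthy threshold — and says nothing about
genes with *no* detectable homology that nevertheless sit inside *cas*
loci. `casforge` combines both signals: trusted similarity hits anchor
loci, genomic context rescues weak hits, and the leftover unannotated
interior genes become candidates for novel Cas families.

## The detection model

A protein with a hit at a Cas family's **gathering cutoff** (the curated
trusted threshold carried in the hit table as `meets_gathering`) is a
**seed**. A gene whose best similarity is weak — any hit with E ≤ 10⁻³ —
is **recruited** when it lies within `window` genes of an already-labeled
gene on the same replicon; recruited genes act as new anchors, and the
procedure iterates until nothing more can be recruited. Because the recruit
condition is monotone in the labeled set, the result is the unique least
fixed point: visiting order cannot matter, which the tests verify against a
brute-force reachability search.

Two parameter choices matter:

* `window = 3` genes. Distance is counted in genes (`gene_index` rank),
  not base pairs, on the grounds that operon structure, not physical
  distance, is what makes neighborhood membership meaningful; most known
  *cas* loci contain at least three genes. Strand and intergenic distance
  are deliberately ignored.
* `weak_e_max = 0.001`. Weak hits below this E-value count as "some
  affinity to known Cas"; anything weaker is treated as noise.

Loci are maximal chains of labeled genes at most `window` apart. Unlabeled
genes strictly inside a chain are kept as `INTERVENING_UNKNOWN` members, so
locus boundaries are always labeled genes. Chains never cross
replicon/contig boundaries, since separate contigs carry no adjacency
information. A chain with no seed member (weak hits only) is discarded —
weak similarity alone, even mutually adjacent, is not considered evidence.

## Classification rules

Subtypes are called from signature families
(`inst/extdata/signature_map.yaml`, editable): the map is data, not code,
because signature inventories evolve. Three rules deserve note:

* **II-C** is defined by composition — exactly {cas9, cas1, cas2} among the
  locus's known-cas annotations — and is called only for loci on complete
  genomes. On a fragment, a truncated II-A or II-B locus is
  indistinguishable from II-C, so the call is withheld (the type II call
  itself still stands).
* **cas4** signals II-B only when cas9 is present, because cas4 also occurs
  in type I systems.
* When two subtype signatures of the same type co-occur, both subtypes are
  reported; the package does not invent a precedence.

Orientation statistics (toxin–antitoxin order, transposase strand
opposition) are measured against the majority strand of the locus's
SEED/RECRUITED members; a strand tie makes the orientation indeterminate
rather than forcing a call. Toxin–antitoxin pairs require adjacency within
two genes.

## Novel-family clustering

Candidates — intervening genes with no hit against any known family — are
reduced at 90% identity with a greedy incremental pass in decreasing length
order, the convention of CD-HIT: identity is identical aligned positions
divided by the *shorter* sequence length. Alignments are global
Needleman–Wunsch with affine gaps under BLOSUM62 (gap open 11, extend 1),
and raw scores are placed on the bit scale with the standard gapped
Karlin–Altschul constants λ = 0.267, K = 0.041, so the "bit score > 60"
edge threshold is comparable to an all-vs-all BLASTP screen. The E-value
used by the known-likeness exclusion is K·m·n·e^(−λS) under the same
constants.

Markov clustering runs on the column-stochastic transition matrix with
self-loops set to each node's maximum incident edge weight, alternating
expansion (matrix squaring) and inflation (entrywise power 1.4 with column
renormalization), pruning entries below 10⁻⁵, until the maximum entry
change falls below 10⁻⁸ (cap 100 iterations). Clusters are the connected
components of the limit's non-zero structure. These numerical defaults are
standard MCL practice and configurable; the tests check agreement with an
independent reference implementation on random graphs.

The "at most 50% identity" property of reported families is exposed as a
*flag* (`passed_diversity`) rather than a member-deleting filter: a cluster
violating it remains visible with its flag down, since silently dropping
members would hide what the clustering actually produced.

## Profile models and refinement

A position-specific scoring model stands in for a full profile HMM: the
refinement loop and its cutoffs are the method of interest here, and they
are agnostic to the emission model. Columns with more than 50% gaps are
dropped; per-column log-odds are
`log2((count + pc·bg) / (n + pc) / bg)` with Laplace-style pseudocount
`pc = 1` (background-weighted), uniform background by default. Scoring is a
global alignment of sequence to columns with a linear per-column gap
penalty (−4 bits).

Refinement recruits database sequences scoring strictly above the worst
current seed, then removes exactly that one worst seed and rebuilds.
Removed seeds return to the database pool and may be re-recruited — the
alternative (permanent removal) is a one-line change, but re-recruitment is
the more faithful reading of "recruiting sequences from the database that
scored higher than the worst seed". On termination, gathering = trusted =
the lowest final-seed score and noise = the highest non-seed score (−∞ if
the database was exhausted, unavailable if it was empty).

The 2-SD length filter uses the population SD and excludes both tails at
`|len − mean| ≥ 2·SD`; with SD = 0 every sequence equals the mean and all
are retained.

## What the synthetic data does and does not show

The generators define the study conditions:

* Replicons: gene lengths ~ 3 × Gamma(shape 9) around a 900 bp mean,
  Poisson intergenic gaps, uniform random strands, uniform residue
  background. Planted loci use standard subtype layouts; core families
  (cas1/cas3/cas9/cas10) carry strong hits, the rest weak hits in
  [10⁻⁶, 10⁻³]; decoy hits on non-planted genes get E in (10⁻³, 10], below
  every threshold, at a configurable false-positive rate.
* Families: members are independent mutants of a common ancestor
  (substitutions only), so pairwise identity is roughly
  1 − 2(1 − ancestor identity) plus chance agreement.
* The refinement fixture (`synth_refinement_family()`) places 5 seeds at
  85% ancestor identity and 3 held-out database members at 98%, emulating a
  database that contains close homologs (conspecific strains) of a family's
  consensus, plus 50 random decoys. Held-out members generated at the
  *same* divergence as the seeds would sit below the worst seed — a seed
  scores its own profile with its idiosyncratic residues counted — so the
  recruit-above-worst-seed rule, by design, only reaches into the database
  for sequences closer to the family consensus than its most divergent seed.
* The cohort: 65 subjects × 4 habitats, habitat mean cas fractions
  stool 0.002, buccal mucosa 0.003, supragingival plaque 0.005, tongue
  dorsum 0.006 (chosen to reproduce the qualitative stool < oral ordering
  at sub-percent abundances), mean-one log-normal subject noise
  (σ = 0.3), 20–60k genes per sample, binomial cas counts.

Passing on these data shows the algorithms implement their definitions —
fixed-point recruitment, exact subtype rules, partition recovery, cutoff
separation — under clean conditions. It does not show robustness to what
real data add: misassemblies, fragmented loci at contig edges, biased
residue composition, paralogy between Cas families, or indel-rich
divergence (the mutator makes substitutions only). Problem sizes in the
tests (replicons ≤ 50 genes, families ≤ 10 members, cohorts of 65 subjects)
were chosen to exercise every code path with clear expected outcomes.

## Degenerate inputs and tie-breaks

* Best-hit reduction: lowest E-value, then highest bit score, then
  lexicographic family id.
* A gene that is both a seed and inside another seed's window stays
  `SEED_KNOWN` (label precedence seed > recruited > intervening).
* Redundancy reduction orders by length descending, ties lexicographic, so
  representative sets are deterministic.
* `paired_ttest` reports t = 0, p = 1 for identical pairs and a flagged
  0-limit p for constant non-zero differences.
* Empty known-reference sets make `exclude_known_like` a warning no-op
  rather than silently excluding nothing.

## Known limitations

* The aligner-backed steps are O(n²) in the candidate count; the package
  targets locus-scale and family-scale inputs, not proteome-wide
  all-vs-all runs.
* Bit scores from global alignments are not BLAST local-alignment bit
  scores; the shared Karlin–Altschul scale makes thresholds comparable in
  spirit, not identical in value.
* No CRISPR-array detection: the pipeline is gene/protein based, and array
  adjacency is not used as evidence.
* The catalytic-residue screen uses global alignment to the reference;
  severely truncated candidates may map positions poorly (a local-alignment
  mode would be the natural extension).
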