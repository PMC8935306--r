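---
title: "Phasing homeologs and detecting Y-chromosome introgression from long-read amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing homeologs and detecting Y-chromosome introgression from long-read amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeophase)
```

# The problem

Allopolyploid genomes carry several diverged subgenomes, so a PCR amplicon
from a polyploid individual is a mixture of sequences of two kinds:
*homeologs* (copies on different subgenomes, typically several percent
diverged) and *alleles* (variants within a subgenome, typically an order of
magnitude less diverged). Building multi-locus phylogenies from such data
requires three inferences that single-locus data cannot make on their own:

1. **Deconvolution** — error-prone long reads of each sample and locus must
   be clustered into the unique template molecules they came from, because a
   usable sequence has to be a consensus of many reads.
2. **Allele/homeolog discrimination** — consensus haplotypes at one locus
   must be partitioned so that allelic variants collapse into one homeolog
   while true homeologs stay apart. We assume divergence between alleles is
   smaller than divergence between homeologs, and that the number of
   homeologs is at most half the sample ploidy (one per subgenome; exactly
   one for a hemizygous Y-linked locus, regardless of ploidy).
3. **Phasing** — because the phase of homeologs *across* loci is unknown,
   the per-locus homeologs must be assigned to consistent subgenome rows
   before loci can be concatenated into a supermatrix.

On top of the phased matrix, the package analyses a hemizygous
**male-specific (Y-linked) locus**: sex-specific presence/absence of
amplification, shared indels, and a tree-incongruence rule that flags
Y-chromosome introgression — the situation where a lineage's Y descends not
from any of its own subgenome donors but from a distant relative.

# The pipeline and its models

## Read clustering and consensus (`clusterReads`, `callConsensus`)

Reads of one (sample, locus) are clustered by greedy farthest-point seeding
from the longest read (up to `expected_k + 1` seeds, where `expected_k` is
ploidy/2, or 1 at a male-specific locus), followed by k-medoids-style
refinement: each read is re-assigned to the nearest interim consensus, and
consensuses are re-polished, for up to three rounds. Similarity is unit-cost
global alignment identity (`1 - d/L`), computed with a banded dynamic
program; unit costs were chosen over scored affine alignment because they
make identity exact and behave well on 5–10% diverged amplicons with
indel-dominated read error. Safeguards:

* reads shorter than half the locus reference are dropped first
  (non-specific amplification products);
* reads below `identity_floor` (default 0.80) to every centroid are set
  aside — the default admits nanopore-error-laden reads of the same template
  (~11% expected error, pairwise identity to its consensus ≈ 0.89) while
  leaving headroom below the 8–10% homeolog divergence this design targets;
* clusters whose consensuses are near-identical (identity ≥ 0.999) merge;
* singleton clusters beyond `expected_k` dissolve into their nearest real
  cluster (a lone over-seeded read otherwise self-attracts);
* clusters below `min_cluster_reads` (default 5) are dropped — a consensus
  needs multiple reads to cancel errors.

The consensus is a per-column majority over a center-star alignment of up to
50 members (chosen deterministically by read id); gap-majority columns are
deleted, and with masking on, base columns whose majority fraction falls
below `mask_threshold` (default 0.7) are written as `N` so that residual
within-cluster variation is marked rather than invented.

The whole procedure draws no random numbers, so results are reproducible by
construction.

## Coverage filter (`depthFilter`)

A (sample, locus) is excluded when its total supporting reads fall below
`factor × ploidy` with `factor = 10`: a hexaploid needs 60 supporting reads,
a diploid 20; a pair exactly at the threshold is retained. The rule scales
with ploidy because a polyploid's reads are split across ploidy/2 templates.

## Allele vs homeolog partition (`partitionHomeologs`)

Consensus haplotypes of one (sample, locus) are agglomerated by
complete-linkage on pairwise p-distances (gap and `N` sites excluded
pairwise). The dendrogram is cut at the largest between-merge gap subject to
at most `expected_k` groups, with one addition: the one-group solution
competes using a virtual ceiling `max_allelic_div` (default 0.02
substitutions/site) as its upper gap bound. This matters for the dropout
case: if one homeolog is missing from the data, a pure gap rule on two or
more groups would happily split the remaining allelic pair into two
"homeologs"; the ceiling makes one group win whenever the top merge is below
the allelic scale. Exact gap ties go to the finer partition (the smaller
maximum within-group divergence, matching the minimax oracle). The default 0.02 sits between the simulated allelic scale
(θ ≈ 0.005, so allele pairs differ by ≈ 0.01) and the homeolog scale
(≥ 0.08), and the dropout guard holds whenever the two scales are separated
by about four-fold. When even the ceiling cut would produce more than
`expected_k` groups, the partition is forced to `expected_k` and flagged; a
separation ratio (min between-group over max within-group divergence) and an
overlap flag per (sample, locus) are reported by `separationDiagnostic()`,
because real data do not always separate the two scales cleanly.

Representatives are chosen by supporting-read count (ties: fewest `N`s, then
name), since downstream phylogenetics wants the best-evidenced sequence per
homeolog.

## Tree engine (`alignSequences`, `distanceMatrix`, `njTree`, `bootstrapSupport`, `rfDistance`)

The internal engine is deliberately simple and fully deterministic:

* **MSA** is center-star progressive alignment anchored, in pipeline use, on
  the locus reference; de-gapping any row returns its input unchanged.
* **Distances** are p-distances over pairwise-comparable columns, with an
  optional Jukes–Cantor correction `d = -3/4 log(1 - 4p/3)`; saturated pairs
  (`p ≥ 0.75`) are set to a configurable maximum and flagged.
* **Trees** are neighbor joining (`ape::nj`) with deterministic taxon
  ordering; negative branch lengths are zeroed with the deficit moved to the
  sister edge.
* **Support** is the nonparametric bootstrap: columns resampled with
  replacement, NJ per replicate, support = percentage of replicates
  containing each reference bipartition. Bipartitions subtended by a
  zero-length branch are reported as support 0 — with no distance signal the
  "replicates" would otherwise all reproduce the same arbitrary resolution.
* **Topology comparison** is the Robinson–Foulds distance
  (`phangorn::RF.dist`), reported raw and normalized by `2(n-3)`.

Maximum-likelihood tree inference is intentionally out of scope: the phasing
logic consumes only topology, patristic distances and supports, which NJ
provides at a fraction of the cost and with no external binaries.

## Phylogeny-guided phasing (`anchorFrame`, `phaseLocus`, `runSubsets`)

Diploid samples are the key: they carry a single sequence per locus, so
their clade membership is unambiguous. On the first locus (by default the
one richest in diploid representatives, then by length), diploids are
clustered into **anchor clades** — one per ancestral subgenome — labelled
`A`, `B`, … in the deterministic order of their smallest member id. Every
further locus is aligned, its NJ tree built, and each sample's homeolog
representatives are matched to the sample's subgenome rows by minimising the
summed patristic distance to the rows' anchor members, over all injective
assignments (at most 3 homeologs × a handful of labels, so exhaustive
matching is exact). A homeolog farther than `denovo_cost` (default 0.05
substitutions/site — above the allelic scale, below the homeolog scale) from
every anchor opens a new, flagged row, never exceeding ploidy/2 rows per
sample; this is the autopolyploid-like case where two homeologs fall in one
diploid clade. Ties are broken deterministically (haplotype name order onto
label order) and flagged; haplotypes carry no identity across loci, so there
is no previous-locus pairing to prefer. Loci missing for a row are
gap-filled; rows present at fewer than half the loci are dropped from the
matrix (the threshold is this package's choice).

`runSubsets()` repeats the whole procedure independently for the full panel
and the autosomal, pseudoautosomal and sex-linked subsets, attaching a
bootstrap NJ tree and a report of well-supported clades (default ≥ 95) to
each. Phasing is single-pass; a `phasingOrderDiagnostic()` reruns it under
random locus orders and reports the fraction of identical assignments, so
order sensitivity is measured rather than hidden.

## Male-specific locus analysis (`presenceAbsence`, `sharedIndels`, `introgressionTest`)

*Presence/absence*: a locus is judged male-specific when at least 80% of
males amplified and no female or monoecious sample did; failing males are
listed as exceptions (rare males of some lineages genuinely fail to
amplify), and any non-male amplification rejects the verdict.

*Shared indels*: maximal alignment-column runs with an identical gap/non-gap
contrast (≥ 2 columns) are reported with their carrier sets, polarized into
insertions/deletions when an outgroup row is supplied. Indels shared across
lineages are strong, alignment-robust evidence of common ancestry of the
Y haplotype.

*Introgression*: the male-specific locus is hemizygous and descends from
exactly one subgenome, so each male's Y should be nearest, on the Y tree, to
the Y of a diploid anchor male whose subgenome label (taken from the phased
genome tree) is among the focal male's own labels. The test flags a male as
an introgression candidate when three conditions hold: the nearest anchor's
label is foreign to every subgenome he carries; the anchor sits *shallow* —
closer than `shallow_frac` (0.5) of the smallest between-label anchor
divergence, the signature of a recent transfer rather than of a missing
anchor; and some bipartition grouping him with that anchor while excluding
his own-label anchors has bootstrap support of at least 70. A foreign
nearest anchor at ordinary species-level depth is reported as `unresolved`
(his subgenome simply has no anchor male), and a shallow foreign placement
without support as `unsupported_discordance`. Formulating the rule through
anchor labels breaks the donor/recipient symmetry: the donor lineage's own
males remain nearest their own label and stay concordant.

# The synthetic-data generator

`simulateDataset()` emulates the statistical structure the analysis assumes,
with full ground truth:

* **Ancestors**: each locus reference evolves along a star phylogeny under
  per-site Jukes–Cantor substitution, with geometric-length indels (mean
  3 bp) at one tenth of the substitution rate — loci in this kind of data
  show both SNPs and indels. Ancestor groups can share a long branch to form
  a distant donor clade.
* **Lineages**: each lineage owns ploidy/2 ancestral subgenomes; every
  sample carries one homeolog template per subgenome per locus, each with
  two allelic sequences at rate `allelic_theta`; males additionally carry
  exactly one Y template (no second allele — the locus is hemizygous);
  an optional introgression event makes one lineage's Y descend from a
  distant donor's ancestor.
* **Reads**: per template, a Poisson number of reads around the nominal
  depth (approximately equimolar pooling implies dispersion), each allele
  chosen at random, passed through a nanopore-like error model (defaults:
  substitutions 1%, insertions 5%, deletions 5% per base). Identical seeds
  give byte-identical FASTQ output.

The **default design** mirrors a real study layout: 24 samples, 23 loci
(8 autosomal, 8 pseudoautosomal, 6 sex-linked, 1 male-specific of 707 bp,
regular loci 700 bp), ploidies 2/4/6 — three diploid annual-type lineages,
two diploid perennial-type lineages on a shared 7% branch, a monoecious
allotetraploid (two donors), and an androdioecious allohexaploid (three
donors) whose Y was introgressed from one perennial lineage, so its Y nests
*inside* the perennial Y clade. Ancestral divergence is 0.08
substitutions/site and allelic θ is 0.005, an order-of-magnitude separation
of the two scales.

One calibration deserves a note. The coverage filter demands
`10 × ploidy` reads and a sample has ploidy/2 templates, so a nominal depth
of 20 reads per template sits *exactly at* the threshold: under Poisson
dispersion roughly half of all (sample, locus) pairs would be excluded by
coin flip, while studies of this design report an exclusion rate of a few
percent. The generator therefore defaults to 30 reads per template, which
reproduces a ~1–3% exclusion rate; the clustering-recovery validation is
still run at 20 reads per template, measuring consensus recovery from the
clustering stage itself.

What the generator does **not** emulate: PCR chimeras between homeologs
(which would stress clustering), quality-score structure, homopolymer-biased
errors, coalescent variation within lineages, or gene conversion between
subgenomes. Passing tests therefore show that the algorithms are correct
under the stated model — clean two-scale divergence and independent errors —
not that real amplicon libraries will behave as well; the separation
diagnostic and the order-sensitivity diagnostic exist precisely because real
data will be messier.

# Validation and problem sizes

The test suite validates each stage against independent oracles (per-site
Bernoulli mutation expectations, exhaustive minimum-distance partitions,
Needleman–Wunsch on pairs, closed-form JC69 and 3-taxon branch lengths,
bipartition enumeration for Robinson–Foulds) and then runs study-scale
end-to-end checks:

* clustering/consensus on the default design at 20 reads/template
  (≥ 95% of templates recovered at ≥ 99% identity);
* homeolog partition vs truth (mean Rand index ≥ 0.95), plus oracle
  equality on all constructed inputs of up to 6 haplotypes;
* phasing at the default depth of 30: every multi-row subgenome clade in the
  all-loci tree recovered with bootstrap ≥ 95 and label-to-donor assignment
  accuracy ≥ 99%;
* introgression detection over 20 replicate histories with the configured
  Y transfer and 20 without (reduced panel of 16 samples and 6 loci per
  replicate to keep each one a few seconds): recipient flagged in ≥ 18/20,
  zero false flags, and the donor-clade indel pattern recovered in the Y
  alignment in most replicates;
* the exact coverage-filter boundary and 100-tree NJ consistency checks.

`scripts/acceptance.R` recomputes all of these from scratch under a
caller-supplied seed and writes them as JSON.

# Known limitations

* Anchoring requires at least two diploid samples at the first locus;
  panels without diploids need externally supplied anchors (not
  implemented).
* The allelic ceiling (`max_allelic_div`) is a fixed scale; datasets whose
  allelic and homeolog divergences overlap will trigger forced/overlap
  flags rather than a model-based resolution.
* The introgression rule needs the donor clade to have at least one male
  anchor in the panel; a donor without sampled males yields `unresolved`,
  not a flag.
* Single-pass phasing can propagate a first-locus anchoring mistake; the
  order diagnostic measures, but does not repair, such sensitivity.
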