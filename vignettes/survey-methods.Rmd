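---
title: "Methods: motif-defined gene-family surveys with auxiaa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-defined gene-family surveys with auxiaa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: what each stage
assumes, which parameters matter, what the synthetic fixtures do and do not
emulate, and where the design was genuinely open.

## The survey procedure

A genome-wide family survey, as practiced for the Aux/IAA auxin repressors
and similar plant families, chains six analyses. `run_pipeline()` executes
them in order; every stage is also an exported function usable alone.

### Family identification

Aux/IAA proteins are defined by four motifs: the `LxLxLx` repressor motif
(I), the `GWPPV/GWPPI` degron (II) through which TIR1/AFB receptors target
the protein for degradation, and the PB1-type dimerization region (III/IV).
We replace profile-HMM domain calls with deterministic degenerate-pattern
matching: a pattern is fixed residues, `x` wildcards and bracket classes;
all match positions are reported.

* **Membership rule** (default: at least two of motifs II, III, IV). The
  rule must not require the degron, or non-canonical members would be lost.
  It is a pluggable predicate.
* **Canonical status**: a member with no motif II hit anywhere is
  *non-canonical*. This is the family's biologically meaningful split — the
  degron-less proteins are long-lived and act as attenuators.
* **Motifs III and IV defaults** (`VKV[SA]MDGAP[YF]LRK`,
  `GDVPWEMF[IV]DSC[KR]RLR`): no consensus strings for these regions are in
  general circulation the way `LxLxLx` and `GWPPV` are, so the packaged
  patterns are package conventions with PB1 flavour, chosen to be long
  enough that chance hits are negligible (20^-13). Users substitute their
  own via the motif-model TSV.

Physicochemical profiles: molecular weight is the sum of average residue
masses plus one water (18.0153 Da); the isoelectric point solves
net-charge(pH) = 0 by bisection on [0, 14] to |charge| < 1e-4. Net charge is
a Henderson–Hasselbalch sum over the termini and the K, R, H (positive) and
D, E, C, Y (negative) side chains; it is strictly decreasing in pH, so the
root is unique and bisection cannot fail. The default pKa table is the
EMBOSS-style set (N-term 8.6, C-term 3.6, K 10.8, R 12.5, H 6.5, D 3.9,
E 4.1, C 8.5, Y 10.1); the table is an argument because published surveys
use several slightly different sets and pI values shift by ~0.1–0.3 between
them.

### Genomic organization

Coordinates are 1-based inclusive everywhere (GFF3 convention); BED input is
converted on read. Gene order within a chromosome is rank by start, ties by
gene id — the index space for tandem and collinearity analysis.

* **Tandem rule** (default: consecutive family genes with ≤ 1 intervening
  gene and ≤ 100 kb between them; both exposed). Published surveys report
  tandem clusters without stating a rule; this pair of thresholds is the
  package's convention and matches the common MCScanX-style practice of
  allowing a single interloper. Singleton "clusters" are not reported.

### Phylogeny

Pairwise distances come from Needleman–Wunsch global alignment with affine
gaps (a length-k gap costs `open + k·ext`), BLOSUM62, open 10 / extend 1 —
any concrete choice is a convention, so all three are parameters. Distance
is `1 − fractional identity`; similarity (identity plus positive-scoring
pairs) is reported but deliberately not used for tree building, being the
less standard transform. UPGMA merges the closest pair, heights d/2,
size-weighted mean updates; ties break on the lexicographically smallest
merged-label pair so trees are bit-reproducible. The progressive MSA merges
profiles along the UPGMA guide tree with profile–profile alignment (column
score = mean pairwise substitution score; gap–residue pairs contribute 0 to
the column score and gaps are opened at the profile level with the same
affine penalties). Bootstrap resamples MSA columns with replacement; each
replicate is re-clustered by average-linkage `stats::hclust` — the same
agglomeration as UPGMA, used for speed — and support is the fraction of
replicates containing each clade of the full-data tree (no consensus tree is
built). The alignment kernels are in C++ (Rcpp) because an 85-protein survey
needs ~3,600 alignments plus 1,000 bootstrap distance matrices.

### Duplication modes and dating

Collinear blocks are maximal chains over externally supplied anchor pairs
(the package does not implement an all-vs-all homology search): per
chromosome pair, dynamic programming finds the longest chain with strictly
monotone order on both genomes (increasing = `same`, decreasing =
`inverted` orientation) and index gaps ≤ 25; chains with ≥ 5 anchors are
extracted greedily and each anchor joins at most one block.

Mode classification is exhaustive and exclusive, by precedence: block →
`wgd_segmental`; tandem cluster → `tandem`; two-sided TE flanking within
10 kb (both an upstream and a downstream element wholly within the window)
→ `transposed`; else `dispersed`. The two-sided rule reflects the
transposed-duplication diagnostic of a gene copy "located among two
transposable elements"; one-sided proximity is not accepted.

Ka/Ks is Nei–Gojobori (1986): per codon position, the synonymous site
fraction is the share of single-base changes preserving the amino acid among
changes not creating a stop (stop-excluded renormalization, so `s + n = 3`
exactly for every sense codon — TGG correctly gets s = 0 although two of its
third-position neighbours are stops). Multi-base codon differences average
(sd, nd) over all orderings of single steps, excluding pathways through
stops; when every pathway is blocked the average is over all pathways with
stop-passing steps counted as nonsynonymous, and the pair is flagged.
Proportions are Jukes–Cantor corrected; p ≥ 3/4 is a saturation error rather
than a silent NaN. Dating is `T = Ks / (2 λ) × 10⁻⁶` Mya at λ = 6.1e-9
substitutions/site/year, with event bins Ks < 0.3 (*Glycine* WGD),
0.3–1.3 closed (legume WGD), > 1.3 (gamma WGT) — the boundaries go to the
legume bin because the published phrasing ("between 0.3 and 1.3") does not
specify openness.

A property worth knowing: when a duplicate pair evolves under purely
synonymous substitution, the NG Ka *estimate* is tiny but not exactly zero —
pathway averaging between endpoint codons that took a synonymous
first-position step on one branch and a synonymous third-position step on
the other (six-fold degenerate Leu/Arg boxes) traverses nonsynonymous
intermediates. The tests bound it at Ka < Ks/20 rather than asserting zero.

### Promoters

1,000 bp upstream of the first coding base (`cds_start`), not the
transcription start — the package interprets "upstream of the start codon"
literally, since annotations of the surveyed genomes rarely carry reliable
TSSs. Plus-strand genes take `[cds_start − 1000, cds_start − 1]`;
minus-strand genes the reverse complement of
`[cds_start + 1, cds_start + 1000]`; chromosome ends truncate with a flag.
Scanning interprets IUPAC degeneracy in the pattern only (the subject is
literal), reports every overlapping match, and reports minus-strand matches
at the forward coordinate of the match start. The packaged element library
carries PLACE-style ids and patterns from public nomenclature; it is a
starting set, not a claim of completeness.

### Expression

RPKM = `count × 10⁹ / (library size × length in bp)`. Z-scores use the
sample (n−1) standard deviation; constant rows map to zeros rather than NaN.
Heatmap ordering uses complete-linkage clustering of Euclidean row
distances. The DE rule is the conjunction fold ≥ 2 (or ≤ 0.5) AND P ≤ 0.05
from a two-sided t test — Welch by default (a flag restores the pooled
classical test), because equal variances are rarely defensible for counts;
no multiple-testing correction is applied, matching the surveyed practice
(a deliberate reproduction, not an endorsement). Fold changes use a +1
pseudo-count on the RPKM scale so all-zero genes are defined (fold 1, not
DE). Paralog divergence is Pearson r of `log2(RPKM + 1)` across samples,
*conserved* iff r ≥ 0.8; the threshold is a package convention (published
verdicts come with no statistic) and zero-variance profiles yield
undefined r, which is reported as diverged with a flag.

## The synthetic fixtures

`load_published_catalog()` ships per-gene tables for the chickpea (22 genes) and
soybean (63 genes) Aux/IAA families: chromosome placement (numbering genes
consecutively along chromosomes, which uniquely reproduces the published
per-chromosome counts and places every listed tandem-cluster member
correctly), degron status, tandem clusters, duplication modes and paralog
pairs with expression-divergence labels. Where the published record is
ambiguous the catalog encodes one consistent assignment, marked here:
of the four soybean genes that are neither WGD/segmental nor tandem,
GmIAA4's transposed call is published; GmIAA29 and GmIAA42 (transposed) and
GmIAA57 (dispersed) are synthetic completions. Likewise the WGD anchor
pairing adds four synthetic pairs — (2,33), (12,20), (23,25), (31,35) — so
that all 57 WGD-labeled genes sit in collinear blocks while GmIAA6 stays
tandem (its biological partner 33 is anchored elsewhere); the (47,49) and
(5,35) pairings are published.

`sim_world()` builds, deterministically under one seed:

* **Sequences.** Family proteins are random backgrounds with the four motif
  instances planted; each WGD or tandem pair descends from a common
  ancestral CDS evolved by `evolve_codon_pair()` — accept/reject single-base
  substitution (synonymous always, nonsynonymous with probability omega
  = 0.2, stops never; motif codons frozen against nonsynonymous change)
  until the synonymous changes per ancestral synonymous site reach the
  target. Pair dS targets: tandem U(0.02, 0.08); WGD 75% U(0.08, 0.28)
  (*Glycine*-aged) and 25% U(0.35, 0.60) (legume-aged). Gamma-aged pairs
  (Ks > 1.3) are not simulated: they saturate the NG/JC estimator, which is
  exactly why the generator's precondition caps dS at 0.75. Non-canonical
  genes get their degron knocked out (GWPPV → GAPPV) and every sequence is
  scrubbed of chance degron matches, so canonical status is guaranteed, not
  probabilistic.
* **Genome.** Genes (family plus decoys) laid out per catalog with 2–5
  exons, 100–400 bp introns, random strands, 1.5 kb intergenic spacing,
  three decoys between non-clustered family genes (so only catalog clusters
  satisfy the tandem rule) and cluster members strictly adjacent. Each
  anchored pair contributes a 5-anchor monotone chain mapping two flanking
  decoys on each side of one gene onto the other's flanks; within a
  chromosome pair all segments follow one orientation (the partner-order
  trend), so neighbouring segments merge into longer blocks exactly as real
  syntenic regions containing tandem arrays do. Transposed-labeled genes get
  TEs planted 2–6 kb away on both sides; all other TEs sit > 10 kb from any
  family gene so the two-sided test cannot fire spuriously.
* **Promoters.** Each family promoter carries 2–4 planted element instances
  (degenerate positions instantiated so the instance contains no other
  library pattern); the remaining kilobase is mutated until it contains no
  library match on either strand. The pipeline's presence table therefore
  equals the planting bookkeeping exactly — the property the generator tests
  rely on.
* **Expression.** Latent per-gene log2 tissue profiles (sd 2.5, base level
  2^N(5,1) RPKM) over the 17 chickpea / 19 soybean tissue panels; a
  conserved pair's partner profile is correlated at rho = 0.95, a diverged
  pair's at 0.2; counts are gamma-mixed Poisson with size 80, the
  technical-replication regime of deep single-library RNA-seq. A separate
  3 + 3 replicate stress experiment plants 4-fold changes in a random 30% of
  genes for the DE stage.

What the fixtures do **not** emulate: real amino-acid composition and
phylogenetic signal (backgrounds are uniform random, so fixture trees test
the algorithms, not subfamily biology), genome-scale synteny beyond the
planted segments, TE families and nesting, isoform structure (RPKM and FPKM
coincide here by construction), biological replicate variance in the tissue
panels, and any real sequence from the surveyed genomes. Passing the
end-to-end tests therefore demonstrates that the pipeline's logic recovers
planted truth exactly at catalog scale — not that the motif models or
thresholds are optimal on real proteomes.

## Numerical choices and degenerate inputs

* Bisection tolerance 1e-4 on charge (not pH): guarantees the reported pI
  has |net charge| below it; the charge curve's slope near neutrality makes
  this ~0.01 pH units for typical proteins.
* UPGMA tie-break: smallest merged-label pair; bootstrap replicates use
  `hclust`, whose own tie behaviour differs, which is immaterial because
  resampled distances are almost surely tie-free.
* JC saturation (p ≥ 3/4) and negative Ks are errors, never silent NA.
* Ragged, non-numeric or duplicate-id expression tables are errors naming
  the offending cell; missing FASTA headers name the line.
* Constant expression rows: Z-score 0; undefined paralog correlation:
  diverged with a flag; all-zero DE groups: fold 1, not DE.
* The whole generator is a function of (catalog, config, seed); the pipeline
  re-seeds from its config, so a rerun writes identical tables.

## Problem sizes in the test suite

The tests run the complete two-species survey (22 + 63 family genes plus
~600 decoy genes, ~4 Mb of simulated genome, 1,000 bootstrap replicates),
the full 61 × 61 sense-codon Nei–Gojobori oracle, 100 random 8-taxon UPGMA
recovery instances, brute-force alignment enumeration at lengths ≤ 5, 1,000
random 200-bp promoters against the degenerate-scanner oracle, 50
purifying-selection recovery pairs of 500 codons, and a 1,000-gene null
simulation of the DE rule. These sizes were chosen as the smallest at which
each property is sharp: count-valued results are exact, and stochastic ones
(bootstrap spread, type-I error, Ks recovery) sit well inside their stated
bounds.

## Known limitations

* Ka/Ks is counting-based NG; no transition/transversion bias or codon
  frequencies (no ML codon models), so absolute Ks on real data runs low
  for diverged pairs, and gamma-WGT-aged pairs are out of reach.
* Collinearity needs anchors from an external homology search; the package
  chains them but does not produce them.
* The bootstrap maps support onto the full-data topology; it does not build
  consensus trees.
* Membership calling is pattern-based; distant family members with degraded
  motifs need a profile-HMM upstream, which is explicitly out of scope.
* The DE rule reproduces the uncorrected 2-fold/0.05 practice of the
  surveyed literature; treat its calls accordingly.
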