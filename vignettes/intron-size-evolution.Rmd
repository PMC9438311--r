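---
title: "Methods: intron size evolution across a synthetic phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intron size evolution across a synthetic phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`intronevo` re-implements, as a tested pipeline, a comparative-genomics
analysis of spliceosomal intron length evolution across a clade of
vertebrate-like genomes: cataloguing introns from annotation, detecting the
bimodal log-scale size distributions characteristic of teleost fishes,
mapping introns across species by alignment, reconstructing ancestral
intron sizes by maximum parsimony, quantifying cross-species size
association, scanning functional terms for depletion among short-intron
genes, and detecting conserved sequence inside long introns. Because the
original observations derive from an annotation release spanning 172 real
genomes, the pipeline is exercised end-to-end on a synthetic cohort whose
generative model is fully known, so that every stage can be validated
against ground truth rather than against irreproducible database snapshots.

# The synthetic cohort

## Species tree

The default cohort has 12 species: a two-species outgroup (`O1`, `O2`),
five background species (`N1`–`N5`, mammal-like: no contraction), and a
five-species monophyletic *contracted* clade (`C1`–`C5`, teleost-like).
Branch lengths are in substitution-model time units; the contracted clade
sits on a long stem (0.6) with within-clade paths of about 1.1–1.75, so
the drift acting on its branches has a total path of about 1.7–1.75 units
per leaf. A `random-birth` mode grafts random subtrees with the same
stem/depth structure, keeping the contracted clade monophyletic by
construction.

## Intron size model

Intron sizes evolve multiplicatively: Brownian motion on the log2 scale
(`log2_sigma`, default 0.2 per sqrt unit branch length) with a clade
drift (`log2_drift_contracted`, default −3 per unit length) on every
branch inside the contracted clade, including its stem. Sizes reflect at a
hard lower boundary — the biologically irreducible intron size. Reflection
rather than truncation is used so that probability mass accumulates in a
spike just above the floor, which is how extant teleost distributions
behave (a sharp peak at ~76 bp).

The floor is *per intron*, not global: each intron draws an irreducible
size at family creation, and every species reflects at that same value.
A single global floor would collapse the contracted clade's short-intron
population to a point mass at 76 bp, which destroys the spread of
clade-minimum lengths that the antimode, the depletion scan and the
conservation set selection all depend on. Per-intron floors are also the
more realistic reading: real introns differ in how much sequence they must
keep to splice.

Intron classes and floors:

* **short free** introns (about half of all introns): floor
  `76 bp * 2^|N(0, 0.55)|`, i.e. a decaying spectrum over roughly
  76–350 bp. Under the default drift, contracted-clade copies glue to
  their floors, producing the minimal-size spike (>25% of free introns in
  76–100 bp) and its decaying right shoulder.
* **sub-retained free** introns: floors drawn around a per-gene centre
  uniform in log2 over about 8.45–9.6 (350–780 bp) with 0.1 jitter. The
  per-gene centre models a gene-level size constraint and gives the
  depletion scan a continuum of gene values just above the class
  boundary. First (rank 1) introns of free-class genes are promoted into
  this band with probability 0.5, reproducing the observation that first
  introns are markedly less often short — consistent with
  promoter-proximal regulatory content.
* **retained** introns: floor `1024 bp * 2^|N(0, 0.2)|`. These never fall
  below 1024 bp in any species and model the long, length-conserved
  intron class.

Root sizes are floor plus a headroom draw (`1.2 + |N(2.2, 0.7)|` log2
units for short free introns, `0.8 + |N(1.4, 0.6)|` for sub-retained,
`1.0 + |N(1.8, 0.7)|` for retained). The offsets order the classes in
unconstrained genomes — short (~1 kb) < sub-retained (~2.4 kb) < retained
(~5.8 kb) — which is what makes the cross-clade quantile prediction
monotone in its threshold: each step up in clade-minimal length selects a
class that is also longer in the background clade.

Genes are typed: a fraction of genes (set so that the intron-level
retained fraction equals `retained_fraction`, default 0.3) are
retained-class. Within them, *strong* genes mix retained introns (80%)
with sub-retained ones; a quarter are *weak* — all sub-retained, no intron
at the retained floor. Weak genes are what places the depletion scan's
strongest-depletion threshold just above the 256-bp class boundary: their
largest clade-minimal intron length falls in the 350–780 bp band, so term
membership (planted on retained-class genes) begins immediately above the
short-gene value range instead of jumping to 1024 bp.

The designed consequence, verified by the tests, is that contracted-clade
species have bimodal log2 size distributions with a trough near
256 bp (the short population's shoulder ends near 2^8; the sub-retained
band begins at ~2^8.45), while background species are broadly unimodal.

## Sequences

Exons (uniform 90–200 bp, one canonical transcript per gene, genes
concatenated on one chromosome with 500-bp spacers) evolve under a
Kimura two-parameter model (`subst_rate` 0.06 substitutions/site/unit,
`ts_tv_ratio` 2), simulated exactly per branch from the closed-form
transition probabilities. Intron background sequence is species-private
random sequence — i.e. treated as diverged beyond recognisability, which
makes the conservation scan's null clean. Each retained intron carries a
planted element: a 120-bp master sequence copied into every species with
per-base identity 0.9 (mutations always change the base). Two species'
copies are then ~81% identical, scoring ~75 under unit match/mismatch
scoring — well above the top local-alignment score of random sequence at
the relevant search spaces (~25–30), but far from trivial identity.
Functional terms: 40 terms of ~18 genes; 5 are planted by sampling only
long-intron genes — retained-class genes plus free-class genes whose
promoted first intron lies above the class boundary — the rest sample all
genes uniformly. Associating the planted terms with every long-intron
gene (rather than the retained class alone) is what localises the
depletion scan's strongest signal at the class boundary: membership then
tracks the value spectrum as soon as it crosses 256 bp, so for most terms
the minimal depletion probability falls between 2^8 and 2^9.

What the generator does *not* emulate: intron gain and loss, transposable
elements, alternative splicing, rate heterogeneity across sites, paralogy,
assembly or annotation error (beyond what the QC filter is tested with).
Passing tests therefore show the pipeline's statistical machinery is
correct and calibrated on data matching its assumptions — not that those
assumptions hold in any real genome.

# Pipeline stages and numerical choices

**Cataloguing.** Coordinates are 0-based half-open internally; GFF3/GTF is
converted at the I/O boundary only. Canonical transcript selection is
"flag-else-longest-exonic-span" with lexicographic tie-break. Zero-length
introns are dropped with a warning; introns under 32 bp are kept but
flagged, and species with more than 2.5% of them are excluded by the QC
filter (boundary inclusive).

**Size distributions.** Gaussian kernel density of log2 length on a fixed
grid (2^4–2^20, 512 points), bandwidth 0.25 log2 units — wide enough to
suppress integer-rounding combing near the 76-bp spike, narrow enough to
resolve the trough at 2^8 from the peak at 2^6.25. The antimode is the
density minimum between the two highest peaks in a stated window;
unimodal densities return `NA`.

**Orthology.** Spliced transcripts carry one meta-symbol per exon–exon
junction. Global alignment over the extended alphabet scores meta–meta
+10, forbids meta–base outright, and uses +1/−1 bases with a linear −2
gap. The large meta bonus makes intron positions attract, which is the
point of the construction; the exact values are this package's choice and
are configurable. Meta symbols are rank-agnostic in scoring; orthology
derives from which metas pair. Alignment is C++ (two-row DP with a byte
traceback); a brute-force recursion over ≤15-symbol toys is the oracle in
the tests.

**Distances and tree.** Transition/transversion counts are pooled across
families before applying the K2P closed form (robust for short
alignments; per-family averaging is available). The distance stage pools a
deterministic evenly-spaced subset of families (default 24, tens of
kilobases of aligned exon per pair) — enough for distances with
negligible sampling error at the simulated rates while bounding the
quadratic alignment cost. Neighbour joining is delegated to `ape::nj`
(the reference implementation of Saitou–Nei agglomeration); negative
branch lengths are clamped to zero with a warning. Rooting bisects the
branch separating the outgroup; node labels are assigned in post-order,
so repeated runs give identical node ids.

**Ancestral sizes.** Lengths are discretised to integral `10*log2` states
(round-half-even). Sankoff parsimony uses linear cost `|Δstate|` over a
lattice spanning the observed states plus a 10-state margin (linear cost
never places an optimum outside the observed hull; the margin is a safety
check). The bottom-up pass uses the O(states) distance-transform form of
the min-convolution; the top-down pass breaks ties toward the state
closest to the parent, then the smallest state (at the root: smallest).
The smallest-state root rule slightly favours small ancestral states when
the character is ambiguous; on the cohort this biases background-leaf
cumulative changes non-negative, which is why the clade-contrast test can
require strict negativity only of contracted leaves. Missing species
contribute all-zero cost vectors. Mode lines follow the stated recipe:
2-D state histogram (introns > 75 bp), column standardisation, separable
Gaussian blur (sd 6 states, kernel truncated at 4 sd, renormalised at the
grid edges so boundary peaks are not pulled inward), per-column local
maxima, nearest-peak chaining across columns (gap tolerance 3 columns),
and a small normal smoothing along each line.

**Association.** Mutual information uses the plug-in estimator on integral
log2 bins, reported in bits; the permutation test permutes one margin and
uses the add-one p-value. Both margins' entropies are constant under
permutation, so only the joint entropy is recomputed — 10,000 permutations
are cheap. The quantile cross-prediction and the size-partitioned
correlations follow the definitions exactly; the correlation ratio is
flagged unreliable when `|r_short| < 0.05`.

**Depletion.** The gene statistic is max-over-introns of
min-across-clade length; thresholds default to every distinct observed
value (≤512 after downsampling); depletion p is the lower-tail
hypergeometric via `phyper`. No multiple-testing correction is applied
(raw curves are the object of interest); the number of terms tested is
reported.

**Conservation.** The recursive aligner reports the optimal local
alignment, masks the seed interval with a sentinel, and repeats until the
score drops below `min_score` (default 20 = a 20-bp exact match under
+1/−1 with gap open −4 / extend −1; a gap of length L costs 4 + L). Seed
intervals are disjoint by construction; partner intervals may overlap.
Pairs with search space over 1e8 are skipped. Controls re-align a
non-orthologous reference intron of similar length (nearest length,
preferring within ±25%, never the same family) against the same partner
introns; the null model is the least-squares fit of log top score on log
search space with flagging above the 95th percentile of control
residuals (natural logs; the base cancels in percentile flagging). The
repeat filter uses a 31-mer seeded genome hit counter (stride 10, loci
clustered by diagonal, counted when k-mer support covers ≥50% of the
query); the synthetic cohort's introns are unique by construction, so the
cohort-scale drivers skip the counting and the counter is exercised on
constructed repeats in the tests. Scans in the drivers use three partner
species: every partner carries the planted element and only the maximum
over partners is scored, so additional partners add cost, not signal.

# Problem sizes

The study cohort is 12 species x 200 families (~1,500 introns, ~2 Mb per
genome). The analysis drivers and tests also use reduced cohorts
(30–100 families) where the quantity under test does not need the full
cohort — sweeps over drift, determinism checks, and toy-oracle
comparisons. These sizes were chosen so the full validation runs on a
single CPU in minutes while keeping every statistic comfortably inside
its designed operating range (e.g. >1,000 paired introns for MI, >250
introns in the conservation long set, >50 control points for the null
model).

# Known limitations

* The orthology assumes conserved intron positions and single-copy
  families; intron gain/loss and paralogy are out of scope.
* Sankoff parsimony with linear costs understates change on long
  branches and inherits the tree; no uncertainty is attached to ancestral
  states.
* The plug-in MI estimator is biased upward at small n; only
  permutation p-values, not raw MI, should be compared across very
  different sample sizes. Bias-corrected estimators are deliberately not
  included.
* The search-space null model only partially compensates for space: its
  residuals still trend with seed length, as the control panels of the
  corresponding real-data analysis also show. Flagging is therefore
  calibrated against controls at matched spaces, not an absolute score
  threshold.
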