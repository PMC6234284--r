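---
title: "Detecting recent marine-freshwater transitions from amplicon data"
author: "habitatscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recent marine-freshwater transitions from amplicon data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The salinity divide between marine and freshwater environments is one of
the strongest barriers in microbial ecology: most lineages are confined
to one side of it, yet closely related marine and freshwater taxa turn up
throughout the bacterial tree. Each such pair implies that an ancestral
lineage crossed the divide at some point. How recently, and in which
taxonomic groups, can be read off 16S rRNA V4 amplicon data — if the
analysis is built to resolve it.

`habitatscan` implements that analysis as a reusable pipeline:

1. **Multi-threshold clustering.** Pairwise sequence distances and
   farthest-neighbor (complete-linkage) clustering at *every* distance
   cutoff on a 0.001 grid, from unique sequences down to the cutoff where
   everything collapses into one cluster.
2. **The shared-identity scan.** For each taxonomic group and each
   marine-freshwater sample pair, the highest identity threshold at which
   the two samples still share a cluster — equivalently, the largest
   identity at which the pair's cluster-level Jaccard distance drops
   below 1. Because sequence divergence accumulates with time, this
   threshold is a proxy for the recency of the group's most recent
   habitat transition: identical sequences in both habitats imply a very
   recent crossing, while sharing only below ~77% identity implies an
   ancient split into habitat-exclusive clades.
3. **Phylogenetic habitat separation.** Unweighted and weighted UniFrac
   over a rooted tree, pairwise between samples and between pooled
   habitat assemblages per group, with PerMANOVA for overall separation
   and independent-swap null ensembles with one-sample z tests for
   per-group structure.
4. **Shared-taxon statistics.** Taxa observed (count > 0) in at least one
   marine and one freshwater sample of the *unrarefied* table, per-group
   totals and shared fractions, accumulation curves over sampling sites,
   and median-based habitat fold-enrichment.
5. **A detection-limit model** quantifying how often dilute populations
   are missed entirely by a sequencing library, and how many times an
   immigrant lineage must arrive before it escapes ecological drift.

A synthetic community generator with controllable transition history
makes every stage testable without external data.

## Distances and clustering

Distances are fractional: differences divided by compared columns.
Comparison for a pair starts at the first and ends at the last column
where both sequences carry a base (terminal gaps are ignored); both-gap
columns and columns with an `N` in either sequence are excluded; a
maximal run of gap columns in one sequence counts as a single difference.
This one-gap convention is the default of the standard amplicon distance
tools, and matters because an indel event spanning several columns is one
evolutionary event, not several. Where a different convention was
conceivable (penalizing terminal gaps, counting `N` columns), we chose
the permissive reading and say so here rather than inferring intent.

Farthest-neighbor clustering admits a merge at cutoff *t* only when *all*
cross-pair distances are at most *t*, so a cluster formed at identity
threshold 1 − *t* is internally consistent at that identity — the
property the scan statistic relies on. Merge order is deterministic: ties
are broken by the lexicographically lowest pair of smallest member
indices. Partitions are materialized on a grid with step 0.001 (an
identity precision of 1,000); the grid subsumes the coarser 1/290 spacing
implied by a 290-position amplicon. Partitions are nested across the grid
by construction, and the test suite verifies every run against an
independent O(n³) re-implementation that recomputes cluster-pair maxima
from the original matrix at every step.

The scan statistic itself is symmetric in its two samples, lands on the
grid, equals 1 exactly when the samples share an identical sequence, and
is monotone: adding a sequence to either sample can only raise it. Pairs
where either sample lacks the group are counted as skipped, never
silently dropped. Samples enter this analysis unrarefied: a single read
is evidence of presence, and rarefaction would discard exactly the
near-detection-limit immigrants the analysis is about.

## UniFrac, nulls, PerMANOVA

Unweighted UniFrac is the fraction of branch length leading exclusively
to one assemblage's tips, out of the branch length leading to either; it
is 1 exactly when the assemblages share no branch — phylogenetically
disjoint subtrees. The weighted variant uses the classic normalized
branch-proportion form Σb·|p_A − p_B| / Σb·(p_A + p_B). Both are checked
against a brute-force oracle that enumerates every branch's descendant
set independently.

Group-level distances pool all marine samples into one assemblage and all
freshwater samples into another, on the group's extracted subtree, after
the standard inclusion filter: a group is analyzed when it appears in at
least 3 samples per habitat and contains at least 5 taxa, and any sample
contributing fewer than 500 reads of the group is excluded for that group
only.

Significance of per-group structure is assessed against independent-swap
randomizations of the group's presence-absence taxon-by-sample matrix:
2×2 checkerboard submatrix swaps that preserve every row and column sum
exactly, so the null keeps each taxon's occupancy and each sample's
richness while scrambling co-occurrence. The chain burns in for 10×cells
attempted swaps and thins by 1×cells attempts between draws; these chain
parameters are ours (only the algorithm family and the ensemble size of
1,000 are standard), as is the decision to randomize the taxon-by-sample
matrix and re-pool habitats afterwards rather than randomizing the pooled
assemblages. The observed statistic is compared by a one-sample z test;
we use the upper tail, since habitat grouping can only inflate the
between-habitat distance above its null, and apply a Bonferroni
correction across groups. A matrix with no swappable checkerboard returns
the original with a warning rather than pretending to mix.

Overall habitat separation uses a one-factor permutation PerMANOVA:
pseudo-F from squared distances with SS_total = Σ_{i<j} d²/N, R² =
SS_between/SS_total, and p = (1 + #{F_perm ≥ F_obs})/(1 + n_perm) over
999 label permutations by default. The implementation is cross-checked
against `vegan::adonis2` in the tests. One caveat the tests encode: with
few samples the attainable minimum p is limited by the label permutations
that reproduce the habitat split exactly (probability 2(k!)²/N! per
draw), so claims of p ≤ 0.001 need roughly ten samples per habitat.

Rarefaction (for the UniFrac analyses only) subsamples each library
without replacement to an even depth, 9,827 reads per sample by default,
dropping and reporting samples below depth.

## The detection model

Assuming reads sample cells in proportion to abundance, the read count of
a population at density ρ within a community at density C is binomial
with p = ρ/C over N draws. At ρ = 1 cell/ml, C = 500,000 cells/ml and
N = 150,000, the population is missed entirely 74% of the time and yields
exactly one read 22% of the time — populations with billions of cells in
a lake layer (density × 10⁶ ml/m³ × area × depth) are routinely invisible.
The binomial is canonical; a Poisson form is exposed and agrees to four
decimals whenever p < 10⁻⁴. Separately, a beneficial immigrant with
selective advantage s escapes drift with probability ≈ 2s per arrival
(branching-process approximation), so it must arrive 1/(2s) times on
average before establishing: five times at a 10% advantage, five hundred
at 0.1%.

## The synthetic community generator

The generator is the package's testbed and defines the conditions under
which the pipeline's accuracy claims are made.

* **Tree.** Pure-birth with unit rate, rescaled to a root height of 0.35
  expected substitutions per site, so anciently split clades sit at raw
  distances around 0.3–0.45 — the regime where habitat-exclusive groups
  share clusters only below ~77% identity.
* **Transitions.** The root is marine; each transition flips the habitat
  of a small internal clade. The stem node is rescaled so the nearest
  cross-habitat tip pair sits at exactly the requested fractional
  divergence d (converted through the equal-rates saturation formula
  p = ¾(1 − e^{−4t/3})), and both child subtrees are compressed far below
  the stem so the flipped and sister lineages behave as tight, recently
  diverged populations. Candidate stems must additionally leave a margin
  of four binomial standard errors between d and the surrounding
  background divergence; without that margin, complete linkage can merge
  background clusters before the transition pair and the event becomes
  unrecoverable in principle. Infeasible requests (d below one
  substitution of resolution, or no placement deep enough) raise errors
  rather than degrading silently.
* **Engineered divergence.** Sequences evolve site-independently under
  the equal-rates four-state model, with one deliberate exception: the
  two stem branches flanking a transition contribute no random
  substitutions (their length is shifted onto the parent edge, leaving
  all other distances untouched) and exactly round(d·L) randomly chosen
  sites of the flipped clade are substituted instead. A freely evolved
  stem would realize d only up to a binomial error of several sites
  (±0.025 at d = 0.23 for L = 290), which would swamp the ±2/L agreement
  the generator promises between requested and realized divergence; fixing
  the substitution count realizes the requested divergence to within
  rounding plus the (negligible) residual evolution of the compressed
  subtrees.
* **Abundances.** Log-normal relative abundances (meanlog 0, sdlog 1.5 by
  default — heavy-tailed, as observed aquatic communities are), with a
  configurable fraction of taxa rescaled to an expected count below one
  read per sample, because near-detection-limit taxa are where the
  shared-taxon analysis earns its keep. The abundance distribution of
  real systems is not settled; log-normal is our modeling choice, flagged
  as such.
* **Sampling.** Library sizes uniform on a configurable interval (the
  exact distribution is immaterial); counts multinomial per sample. Taxa
  native to the sample's habitat carry full weight; cross-habitat taxa
  are down-weighted by an immigrant factor (5×10⁻⁴ by default), so shared
  taxa appear at trace abundances near the detection limit. Setting the
  factor to 0 turns cross-habitat observation off entirely, which the
  truth record reflects.
* **Determinism.** One integer seed drives every draw; identical
  specifications produce byte-identical FASTA, newick, TSV and JSON
  outputs, and the pipeline manifest records parameters, seeds and output
  checksums so reruns are verifiably identical.

What the generator does **not** emulate: among-site rate heterogeneity,
indels, chimeras, primer or extraction bias, compositional sequencing
artifacts, or ecological correlation between samples. Passing tests on
synthetic data therefore demonstrate algorithmic correctness and
recoverability under the stated model, not robustness to the full
messiness of environmental surveys.

## Numerical choices

Cutoff comparisons use an absolute tolerance of 10⁻¹². The scan reports
identity 1 − c* where c* is the first grid cutoff at or above the merge
height, so reported identities are conservative by at most one grid step.
Zero-abundance medians in fold-enrichment are replaced by half the
smallest nonzero per-sample group relative abundance observed in the
call (our rule; any fixed pseudo-abundance would do, and the flag
`pseudo_used` marks affected groups). Accumulation curves hold the full
opposite-habitat site set fixed and accumulate one habitat's sites,
enumerating all orderings exactly when there are no more of them than
requested and sampling otherwise. An optional lineage-rank argument
restricts clustering within groups (the scan clusters per phylum by
default), mirroring the practice of splitting large distance matrices
along a coarse classification.

## Problem sizes

The shipped analyses and tests run at desk scale by choice: communities
of 16–48 taxa, 6–20 samples, 290-position alignments, 60–1,000 null draws
and 99–999 permutations. Every statistic here is exact or
seed-deterministic at these sizes; scaling to survey-size data is a
matter of compute, not of different code paths — with the caveat that the
all-pairs distance matrix grows quadratically in sequences, which is
exactly why group-wise clustering exists.

## Known limitations

The scan dates sharing, not direction: it does not infer which habitat
was ancestral. Thresholds are proxies ordered by recency, not calendar
ages. Complete linkage is conservative: a single divergent member delays
a cluster's merge, so scan values can understate sharing that
average-linkage methods would report. The swap null conditions on margins
only; nulls preserving other structure (spatial, temporal) are out of
scope. Differential-abundance testing beyond the median fold-change
summary is deliberately not included.
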