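# habitatscan

Microbial lineages only rarely cross the salinity divide between marine
and freshwater habitats — yet closely related marine and freshwater taxa
are scattered across the bacterial tree, and every such pair records a
transition. `habitatscan` is an R package for detecting and ranking these
recent habitat transitions from aligned 16S rRNA V4 amplicon data, built
for microbial ecologists analyzing cross-system surveys.

## What it computes

The core statistic works directly at the sequence level, with no fixed
OTU definition. For each taxonomic group, pairwise distances d(i,j)
(one-gap convention) feed a farthest-neighbor (complete-linkage)
clustering evaluated at every cutoff t on a 0.001 grid. For a marine
sample M and freshwater sample F, the package reports

    T(M, F) = max { 1 − t : some cluster at cutoff t contains
                            a sequence of M and a sequence of F }

— the highest identity threshold at which the pair still shares a
cluster, equivalently the largest identity at which the pair's Jaccard
distance J = 1 − |A∩B|/|A∪B| over cluster sets drops below 1. Identical
sequences in both habitats give T = 1 (a very recent transition); groups
split anciently into habitat-exclusive clades share only at T ≲ 0.77.

Around the scan, the package provides the standard supporting analyses:
unweighted and weighted UniFrac (pairwise and pooled by habitat per
group) with independent-swap null ensembles, one-sample z tests and
permutation PerMANOVA; shared-taxon reports, site-accumulation curves
and median fold-enrichment; a binomial detection-limit model
P(k reads) = C(N,k) p^k (1−p)^(N−k) with p = ρ_pop/ρ_community; the drift
barrier 1/(2s) expected arrivals before establishment; and a seeded
synthetic community generator with controllable transition history that
makes the whole pipeline testable end to end.

## Worked example

Simulate a community of 24 taxa with a single marine-to-freshwater
transition at 4% sequence divergence, then scan all marine-freshwater
sample pairs:

```r
library(habitatscan)

spec <- synthetic_spec(n_taxa = 24, n_transitions = 1,
                       transition_divergences = 0.04,
                       n_marine_samples = 3, n_freshwater_samples = 3,
                       library_size_range = c(2000, 2000),
                       rare_fraction = 0, immigrant_weight = 0, seed = 5)
comm <- simulate_community(spec)
comm$truth$transitions[, c("n_tips_flipped", "requested_divergence",
                           "realized_divergence")]
#>   n_tips_flipped requested_divergence realized_divergence
#> 1              2                 0.04                0.04

lin <- make_lineage(comm$tree, cut_fractions = c(phylum = 1.0, class = 0.6,
                                                 order = 0.4, family = 0.25,
                                                 genus = 0.12))
scan <- group_scan(comm$seqs, comm$counts, comm$metadata, lin, rank = "phylum")
scan_tables(scan)$summary[, c("group", "median", "min", "max")]
#>   group median   min   max
#> 1 Phy01  0.958 0.958 0.958
```

The scan recovers the engineered event: every one of the nine sample
pairs first shares a cluster at identity 0.958 ≈ 1 − 0.04 (the grid
rounds the realized 12-substitution divergence of 12/290 up to the next
0.001 cutoff). The detection model explains why such events hide in real
surveys:

```r
detection_probability(1, 5e5, 150000, k = 0)   # 0.7408 — missed entirely
detection_probability(1, 5e5, 150000, k = 1)   # 0.2222 — a single read
establishment_appearances(0.1)                 # 5 arrivals before establishment
```

A population at one cell per ml of a half-million-cells-per-ml community
goes completely unsequenced 74% of the time even in a 150,000-read
library, yet numbers ~10 billion cells in a one-meter layer of a small
lake (`census_size(1, 1e4, 1)`).

## The analysis workflow

Numbered drivers under `analysis/` run the full study on a reference
synthetic community (48 taxa, 8+8 samples, transitions at 2%, 8% and 25%
divergence) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_community.R   # community + truth + validation
Rscript analysis/02_cluster_and_scan.R     # multi-threshold scan by phylum
Rscript analysis/03_unifrac_separation.R   # rarefaction, UniFrac, PerMANOVA, swap nulls
Rscript analysis/04_shared_taxa.R          # shared taxa, accumulation, enrichment
Rscript analysis/05_detection_limits.R     # detection and drift arithmetic
```

On this community the habitat PerMANOVA gives F = 76.4, R² = 0.845,
p = 0.001 (unweighted UniFrac, 999 permutations), 15 of 48 taxa are
shared across habitats through immigrant-level counts, and the
community-wide pooled habitat UniFrac of 0.514 sits 11 standard
deviations above its independent-swap null.

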