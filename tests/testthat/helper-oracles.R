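# Independent oracles used across the suite. These deliberately take the
# slow, from-first-principles route so they share no code path with the
# implementations they check.

# complete-linkage partition at one cutoff, recomputed from scratch at every
# step from the original distance matrix (O(n^3) set merging); same
# tie-break rule as the implementation (lowest pair of smallest members)
oracle_complete_partition <- function(dm, cutoff) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1L) break
    best_i <- best_j <- 0L
    best_d <- Inf
    best_key <- c(Inf, Inf)
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq(i + 1L, length(clusters))) {
        cd <- max(dm[clusters[[i]], clusters[[j]]])
        k1 <- min(clusters[[i]][1], clusters[[j]][1])
        k2 <- max(clusters[[i]][1], clusters[[j]][1])
        better <- cd < best_d - 1e-12 ||
          (abs(cd - best_d) <= 1e-12 &&
             (k1 < best_key[1] || (k1 == best_key[1] && k2 < best_key[2])))
        if (better) {
          best_d <- cd; best_i <- i; best_j <- j; best_key <- c(k1, k2)
        }
      }
    }
    if (best_d > cutoff + 1e-12) break
    merged <- sort(c(clusters[[best_i]], clusters[[best_j]]))
    clusters <- clusters[-c(best_i, best_j)]
    clusters[[length(clusters) + 1L]] <- merged
  }
  lab <- integer(n)
  for (cl in clusters) lab[cl] <- cl[1]
  lab
}

# UniFrac by explicit per-branch descendant enumeration via phangorn
oracle_unifrac <- function(tree, a, b, weighted = FALSE,
                           counts_a = NULL, counts_b = NULL) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  tips <- tree$tip.label
  if (weighted) {
    ta <- sum(counts_a); tb <- sum(counts_b)
    num <- den <- 0
    for (e in seq_along(desc)) {
      dt <- tips[desc[[e]]]
      pa <- sum(counts_a[intersect(names(counts_a), dt)]) / ta
      pb <- sum(counts_b[intersect(names(counts_b), dt)]) / tb
      num <- num + tree$edge.length[e] * abs(pa - pb)
      den <- den + tree$edge.length[e] * (pa + pb)
    }
    num / den
  } else {
    uniq <- both <- 0
    for (e in seq_along(desc)) {
      dt <- tips[desc[[e]]]
      in_a <- any(dt %in% a); in_b <- any(dt %in% b)
      if (xor(in_a, in_b)) uniq <- uniq + tree$edge.length[e]
      if (in_a || in_b) both <- both + tree$edge.length[e]
    }
    uniq / both
  }
}

# random aligned character matrix, optionally with gaps
random_alignment <- function(n, L, gap_prob = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  if (gap_prob > 0) m[matrix(runif(n * L) < gap_prob, n, L)] <- "-"
  rownames(m) <- sprintf("s%02d", seq_len(n))
  m
}

# random symmetric distance matrix (continuous, effectively tie-free)
random_distance_matrix <- function(n, seed = 1) {
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.001, 0.6)
  d <- d + t(d)
  rownames(d) <- colnames(d) <- sprintf("s%02d", seq_len(n))
  d
}

# the tiny worked clustering example used in several tests:
# d(1,2)=0.1, d(1,3)=0.5, d(2,3)=0.6
example_dm <- function() {
  d <- matrix(c(0, 0.1, 0.5,
                0.1, 0, 0.6,
                0.5, 0.6, 0), 3, 3, byrow = TRUE)
  rownames(d) <- colnames(d) <- c("s1", "s2", "s3")
  d
}

# small default community spec for tests
test_spec <- function(...) {
  args <- list(n_taxa = 20L, n_transitions = 1L, transition_divergences = 0.05,
               n_marine_samples = 3L, n_freshwater_samples = 3L,
               library_size_range = c(1000L, 1000L), rare_fraction = 0,
               immigrant_weight = 0, seed = 42L)
  args[names(list(...))] <- list(...)
  if (args$n_transitions == 0L && !"transition_divergences" %in% names(list(...)))
    args$transition_divergences <- numeric(0)
  do.call(synthetic_spec, args)
}

# single-phylum lineage so a whole community scans as one group
one_group_lineage <- function(tree) {
  make_lineage(tree, cut_fractions = c(phylum = 1.0, class = 0.6, order = 0.4,
                                       family = 0.25, genus = 0.12))
}

# constructed family whose marine and freshwater members occupy the two
# disjoint clades descending from the root
disjoint_family_fixture <- function(seed = 1, n_taxa = 16) {
  spec <- synthetic_spec(n_taxa = n_taxa, n_transitions = 0,
                         transition_divergences = numeric(0), seed = seed)
  tree <- simulate_tree(spec)
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  tipset <- function(node) tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
  marine_taxa <- tipset(kids[1])
  fresh_taxa <- tipset(kids[2])
  samples <- c("M1", "M2", "M3", "F1", "F2", "F3")
  counts <- matrix(0L, n_taxa, 6, dimnames = list(tree$tip.label, samples))
  counts[marine_taxa, 1:3] <- 600L
  counts[fresh_taxa, 4:6] <- 600L
  metadata <- data.frame(sample_id = samples,
                         habitat = rep(c("marine", "freshwater"), each = 3),
                         site = paste0("site_", samples),
                         depth_class = "surface", stringsAsFactors = FALSE)
  lineage <- data.frame(taxon_id = tree$tip.label,
                        lineage = "PhyA;ClsA;OrdA;FamA;GenA",
                        stringsAsFactors = FALSE)
  list(tree = tree, counts = counts, metadata = metadata, lineage = lineage,
       marine_taxa = marine_taxa, fresh_taxa = fresh_taxa)
}
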