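# Jaccard distance and the cross-habitat shared-identity scan.

# counts matrix helper: rows taxa, cols samples
cmat <- function(m, taxa, samples) {
  matrix(as.integer(m), length(taxa), length(samples),
         dimnames = list(taxa, samples))
}

test_that("Jaccard distance follows the shared-over-union definition", {
  expect_equal(jaccard_distance(c("c1", "c2", "c3"), c("c3", "c4")), 0.75)
  expect_equal(jaccard_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccard_distance(c("a", "b"), c("c")), 1)
  expect_error(jaccard_distance(character(0), character(0)), "undefined")
})

test_that("pair scan returns the highest identity with a shared cluster", {
  # both samples contain the identical sequence: shared at cutoff 0
  d0 <- matrix(c(0, 0, 0.3, 0, 0, 0.3, 0.3, 0.3, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  cl0 <- farthest_neighbor_cluster(d0)
  cn0 <- cmat(c(1, 0, 0,
                1, 0, 1), c("x", "y", "z"), c("M1", "F1"))
  expect_equal(pair_scan(cl0, cn0, "M1", "F1"), 1.0)

  # worked example: marine={s1}, freshwater={s3}, merge at 0.6 -> 0.40
  cl <- farthest_neighbor_cluster(example_dm())
  cn <- cmat(c(5, 0, 0,
               0, 0, 7), c("s1", "s2", "s3"), c("M1", "F1"))
  expect_equal(pair_scan(cl, cn, "M1", "F1"), 0.40)

  # errors: absent sample vs sample without the group
  expect_error(pair_scan(cl, cn, "M9", "F1"), "absent")
  cn_empty <- cn; cn_empty[, "F1"] <- 0L
  expect_error(pair_scan(cl, cn_empty, "M1", "F1"), "no sequences")
})

test_that("pair scan is symmetric, monotone and matches a from-scratch oracle", {
  # oracle: partitions recomputed from scratch at every grid cutoff, sharing
  # detected through the Jaccard distance over cluster-id sets
  oracle_scan <- function(d, counts, a, b, grid_step = 0.01) {
    cuts <- seq(0, 1, by = grid_step)
    for (cu in cuts) {
      lab <- oracle_complete_partition(d, cu)
      ca <- unique(lab[counts[, a] > 0])
      cb <- unique(lab[counts[, b] > 0])
      if (jaccard_distance(ca, cb) < 1) return(1 - cu)
    }
    NA_real_
  }
  for (seed in 1:5) {
    d <- random_distance_matrix(8, seed = seed)
    set.seed(seed + 100)
    counts <- cmat(rbinom(16, 5, 0.5), rownames(d), c("M1", "F1"))
    counts[1, "M1"] <- 1L; counts[2, "F1"] <- 1L  # both non-empty
    cl <- farthest_neighbor_cluster(d, grid_step = 0.01)
    v <- pair_scan(cl, counts, "M1", "F1")
    expect_equal(v, oracle_scan(d, counts, "M1", "F1"))
    # symmetry
    counts_sw <- counts[, c(2, 1)]
    colnames(counts_sw) <- c("M1", "F1")
    expect_equal(pair_scan(cl, counts_sw, "M1", "F1"), v)
    # identity 1 iff the samples share an identical sequence (distance 0)
    pres_a <- counts[, "M1"] > 0; pres_b <- counts[, "F1"] > 0
    has_identical <- min(d[pres_a, pres_b, drop = FALSE]) == 0
    expect_equal(v == 1.0, has_identical)
    # monotonicity: adding a sequence to a sample never lowers the value
    counts2 <- counts
    add <- which(counts[, "M1"] == 0)
    if (length(add) > 0) {
      counts2[add[1], "M1"] <- 1L
      expect_gte(pair_scan(cl, counts2, "M1", "F1"), v)
    }
  }
})

test_that("group scan covers all pairs, skips absences and recovers transitions", {
  s <- test_spec(n_taxa = 24, transition_divergences = 0.04, seed = 5)
  comm <- simulate_community(s)
  lin <- one_group_lineage(comm$tree)
  sc <- group_scan(comm$seqs, comm$counts, comm$metadata, lin, rank = "phylum")
  expect_length(sc, 1L)
  r <- sc[[1]]
  # 3 marine x 3 freshwater -> 9 pair records
  expect_equal(nrow(r$pairs), 9L)
  expect_equal(r$n_pairs_skipped, 0L)
  # one transition at divergence 0.04 -> median within 0.01 of 0.96
  expect_lt(abs(r$summary[["median"]] - 0.96), 0.01)
  # summary median inside [min, max], values on the identity grid
  expect_gte(r$summary[["median"]], r$summary[["min"]])
  expect_lte(r$summary[["median"]], r$summary[["max"]])
  expect_true(all(abs(r$pairs$max_shared_identity * 1000 -
                        round(r$pairs$max_shared_identity * 1000)) < 1e-6))

  # a marine sample emptied of the group causes skipped (not dropped) pairs
  counts2 <- comm$counts
  counts2[, "M01"] <- 0L
  sc2 <- group_scan(comm$seqs, counts2, comm$metadata, lin, rank = "phylum")
  expect_equal(nrow(sc2[[1]]$pairs), 6L)
  expect_equal(sc2[[1]]$n_pairs_skipped, 3L)
  expect_equal(sc2[[1]]$n_marine_present, 2L)

  # a group with no freshwater presence is flagged not evaluable
  counts3 <- comm$counts
  counts3[, c("F01", "F02", "F03")] <- 0L
  sc3 <- group_scan(comm$seqs, counts3, comm$metadata, lin, rank = "phylum")
  expect_false(sc3[[1]]$evaluable)
})

test_that("anciently split groups never share at high identity", {
  # marine and freshwater clades separated by >= 0.23: all pair values <= 0.77
  s <- test_spec(n_taxa = 24, transition_divergences = 0.23, seed = 17)
  comm <- simulate_community(s)
  lin <- one_group_lineage(comm$tree)
  sc <- group_scan(comm$seqs, comm$counts, comm$metadata, lin, rank = "phylum")
  expect_true(all(sc[[1]]$pairs$max_shared_identity <= 0.77 + 1e-9))
})
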