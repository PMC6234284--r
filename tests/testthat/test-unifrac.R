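# UniFrac distances, rarefaction, pooled-habitat group distances.

four_tip <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

test_that("unweighted UniFrac matches hand-enumerated branch sums", {
  tr <- four_tip()
  # disjoint clades share no branch
  expect_equal(unweighted_unifrac(tr, c("A", "B"), c("C", "D")), 1.0)
  expect_equal(unweighted_unifrac(tr, c("A", "B"), c("A", "B")), 0)
  # {A,C} vs {B,D}: both internal branches shared, four tip branches unique
  expect_equal(unweighted_unifrac(tr, c("A", "C"), c("B", "D")), 4 / 6)
  expect_error(unweighted_unifrac(tr, character(0), "A"), "non-empty")
  expect_error(unweighted_unifrac(tr, "A", "nope"), "not present")
})

test_that("weighted UniFrac matches hand-summed branch terms", {
  tr <- four_tip()
  expect_equal(weighted_unifrac(tr, c(A = 3, B = 1), c(A = 3, B = 1)), 0)
  expect_equal(weighted_unifrac(tr, c(A = 1), c(C = 1)), 1.0)
  # A:{A:3,B:1} vs B:{A:1,B:3}: AB stem cancels (p=1 both);
  # tips A and B each contribute |0.75-0.25|; denominator 2+1+1
  expect_equal(weighted_unifrac(tr, c(A = 3, B = 1), c(A = 1, B = 3)), 1 / 4)
  expect_error(weighted_unifrac(tr, c(A = 0), c(B = 1)), "positive total")
})

test_that("both variants agree with the branch-enumeration oracle on random trees", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:16, 1)
    tr <- ape::rtree(n)
    tips <- tr$tip.label
    a <- sample(tips, sample(seq_len(n - 1), 1))
    b <- sample(tips, sample(seq_len(n - 1), 1))
    expect_equal(unweighted_unifrac(tr, a, b), oracle_unifrac(tr, a, b),
                 tolerance = 1e-12)
    ca <- stats::setNames(sample(1:20, length(a), replace = TRUE), a)
    cb <- stats::setNames(sample(1:20, length(b), replace = TRUE), b)
    expect_equal(weighted_unifrac(tr, ca, cb),
                 oracle_unifrac(tr, weighted = TRUE, counts_a = ca, counts_b = cb),
                 tolerance = 1e-12)
  }
})

test_that("unweighted UniFrac agrees with an established implementation", {
  set.seed(3)
  tr <- ape::rtree(10)
  comm <- matrix(rbinom(30, 1, 0.6), 3, 10,
                 dimnames = list(c("s1", "s2", "s3"), tr$tip.label))
  comm[comm[, 1] == 0 & rowSums(comm) == 0, 1] <- 1  # no empty samples
  ref <- as.matrix(picante::unifrac(comm, tr))
  for (i in 1:2) for (j in (i + 1):3) {
    a <- colnames(comm)[comm[i, ] > 0]
    b <- colnames(comm)[comm[j, ] > 0]
    expect_equal(unweighted_unifrac(tr, a, b), ref[i, j], tolerance = 1e-10)
  }
})

test_that("rarefaction conserves depth and the hypergeometric expectation", {
  counts <- matrix(c(50L, 30L, 20L, 10L, 5L, 85L), 3, 2,
                   dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  r <- rarefy(counts, 100, seed = 1)
  expect_true(all(colSums(r) == 100L))
  expect_identical(r[, "s1"], counts[, "s1"])  # depth equals the total

  r2 <- rarefy(counts, 60, seed = 2)
  expect_true(all(colSums(r2) == 60L))
  expect_true(all(r2 <= counts))

  expect_warning(rarefy(counts, 150), "dropping")
  expect_error(rarefy(counts, 0), "positive")

  # mean rarefied count over many seeds approaches depth * proportion
  depth <- 40
  draws <- sapply(1:1000, function(s) rarefy(counts[, 1, drop = FALSE], depth, seed = s)[, 1])
  p <- counts[, 1] / sum(counts[, 1])
  expected <- depth * p
  N <- sum(counts[, 1])
  sd_hyper <- sqrt(depth * p * (1 - p) * (N - depth) / (N - 1))
  se <- sd_hyper / sqrt(1000)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se + 1e-9))
})

test_that("pooled-habitat group UniFrac separates disjoint clades and equals the oracle", {
  # constructed family: marine and freshwater occupy the two disjoint
  # subtrees descending from the family root
  fx <- disjoint_family_fixture(seed = 23)
  res <- pooled_group_unifrac(fx$tree, fx$counts, fx$metadata, fx$lineage,
                              rank = "family")
  expect_equal(nrow(res), 1L)
  expect_equal(res$pooled_unifrac, 1.0)
  # and every pairwise sample distance is 1 as well
  expect_equal(res$pair_median, 1.0)

  # every taxon shared (identical pools) gives 0
  counts_all <- fx$counts
  counts_all[] <- 600L  # everything everywhere
  res0 <- pooled_group_unifrac(fx$tree, counts_all, fx$metadata, fx$lineage,
                               rank = "family")
  expect_equal(res0$pooled_unifrac, 0)

  # pooled value equals the brute-force oracle on a random fixture
  s2 <- test_spec(n_taxa = 12, immigrant_weight = 5e-3, seed = 31,
                  library_size_range = c(3000L, 3000L))
  comm2 <- simulate_community(s2)
  lin2 <- one_group_lineage(comm2$tree)
  lin2$family <- lin2$phylum
  res2 <- pooled_group_unifrac(comm2$tree, comm2$counts, comm2$metadata, lin2,
                               rank = "family", min_group_reads = 1L)
  meta <- comm2$metadata
  pm <- rownames(comm2$counts)[rowSums(comm2$counts[, meta$sample_id[meta$habitat == "marine"]]) > 0]
  pf <- rownames(comm2$counts)[rowSums(comm2$counts[, meta$sample_id[meta$habitat == "freshwater"]]) > 0]
  expect_equal(res2$pooled_unifrac, oracle_unifrac(comm2$tree, pm, pf), tolerance = 1e-12)
  expect_gte(res2$pooled_unifrac, 0)
  expect_lte(res2$pooled_unifrac, 1)
})
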