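# Synthetic community generator: trees, habitat transitions, sequence
# evolution, count tables.

test_that("tree simulation respects size, determinism and scaling", {
  expect_error(synthetic_spec(n_taxa = 1), "at least 2")

  tr2 <- simulate_tree(test_spec(n_taxa = 2))
  expect_equal(length(tr2$tip.label), 2L)
  expect_equal(tr2$Nnode, 1L)

  s <- test_spec(n_taxa = 50, seed = 1)
  expect_identical(ape::write.tree(simulate_tree(s)), ape::write.tree(simulate_tree(s)))

  tr <- simulate_tree(test_spec(n_taxa = 100, seed = 7))
  expect_equal(length(tr$tip.label), 100L)
  expect_gt(sum(tr$edge.length), 0)
  # ultrametric with root height = tree_height
  depth <- ape::node.depth.edgelength(tr)
  tip_depth <- depth[seq_len(100)]
  expect_equal(max(tip_depth), test_spec()$tree_height, tolerance = 1e-9)
  expect_lt(diff(range(tip_depth)), 1e-9)
})

test_that("habitat assignment places transitions at the requested divergence", {
  # no transitions: one habitat, nothing expected to be shared
  truth0 <- assign_habitats(simulate_tree(test_spec(n_transitions = 0)),
                            test_spec(n_transitions = 0))
  expect_true(all(truth0$habitat == "marine"))
  expect_length(truth0$expected_shared, 0)

  # forced identity: divergence 0 yields identical cross-habitat sequences
  s0 <- test_spec(n_transitions = 1, transition_divergences = 0, seed = 9)
  comm0 <- simulate_community(s0)
  hab <- comm0$truth$habitat
  dm <- pairwise_distance(comm0$seqs)
  cross <- dm[names(hab)[hab == "freshwater"], names(hab)[hab == "marine"], drop = FALSE]
  expect_equal(min(cross), 0)

  # two events bracketing 0.01 and 0.20, checked by exhaustive pairwise
  # comparison of the evolved sequences
  s2 <- test_spec(n_taxa = 32, n_transitions = 2,
                  transition_divergences = c(0.01, 0.20), seed = 3)
  comm2 <- simulate_community(s2)
  hab <- comm2$truth$habitat
  dm <- pairwise_distance(comm2$seqs)
  tol <- 2 / s2$alignment_length
  for (i in 1:2) {
    flipped <- comm2$truth$flipped[[i]]
    others <- setdiff(names(hab)[hab != hab[flipped[1]]], flipped)
    realized <- min(dm[flipped, others, drop = FALSE])
    expect_lt(abs(realized - s2$transition_divergences[i]), tol + 1e-12)
    # tree-implied (expected-scale) divergence is exact
    expect_equal(comm2$truth$transitions$realized_divergence[i],
                 s2$transition_divergences[i], tolerance = 1e-9)
  }

  # infeasible: below one substitution of resolution
  expect_error(
    assign_habitats(simulate_tree(test_spec()),
                    test_spec(transition_divergences = 0.001)),
    "resolution")
})

test_that("sequence evolution follows the equal-rates model", {
  s <- test_spec(n_taxa = 10)
  tr <- simulate_tree(s)

  # zero branch lengths: all sequences identical
  tr0 <- tr
  tr0$edge.length[] <- 0
  m0 <- evolve_sequences(tr0, s)
  expect_true(all(m0 == rep(m0[1, ], each = nrow(m0))))

  # saturation: two tips at 0.5 substitutions/site apart, long alignment,
  # raw mismatch near the closed-form expectation 0.75*(1 - exp(-4*0.5/3))
  sL <- test_spec(n_taxa = 2, alignment_length = 10000L, n_transitions = 0, seed = 11)
  tr2 <- ape::read.tree(text = "(a:0.25,b:0.25);")
  m <- evolve_sequences(tr2, sL)
  p_exp <- 0.75 * (1 - exp(-4 * 0.5 / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(mean(m["a", ] != m["b", ]) - p_exp), 3 * se)

  # determinism: identical matrices on repeated calls
  expect_identical(evolve_sequences(tr, s), evolve_sequences(tr, s))
})

test_that("count sampling conserves library sizes and habitat structure", {
  s <- test_spec(library_size_range = c(100L, 100L))
  truth <- assign_habitats(simulate_tree(s), s)
  cs <- sample_counts(truth, s)
  expect_true(all(colSums(cs$counts) == 100L))

  # immigrant weight 0: no taxon observed outside its home habitat
  hab_s <- setNames(cs$metadata$habitat, cs$metadata$sample_id)
  for (tx in rownames(cs$counts)) {
    away <- cs$metadata$sample_id[hab_s != truth$habitat[tx]]
    expect_true(all(cs$counts[tx, away] == 0))
  }

  # determinism
  cs2 <- sample_counts(truth, s)
  expect_identical(cs$counts, cs2$counts)

  # rare tail: with rare_fraction = 0.5 a large share of taxa averages
  # fewer than one read per sample
  sr <- test_spec(n_taxa = 40, rare_fraction = 0.5, immigrant_weight = 1e-3,
                  library_size_range = c(10000L, 10000L), seed = 13)
  truthr <- assign_habitats(simulate_tree(sr), sr)
  csr <- sample_counts(truthr, sr)
  mean_per_sample <- rowMeans(csr$counts)
  expect_gte(sum(mean_per_sample < 1), 0.8 * round(0.5 * 40))
})

test_that("full communities are deterministic and internally consistent", {
  s <- test_spec(immigrant_weight = 5e-4)
  c1 <- simulate_community(s)
  c2 <- simulate_community(s)
  expect_identical(c1$seqs, c2$seqs)
  expect_identical(c1$counts, c2$counts)
  expect_identical(ape::write.tree(c1$tree), ape::write.tree(c2$tree))

  # written files are byte-identical too
  d1 <- file.path(tempdir(), "comm_a"); d2 <- file.path(tempdir(), "comm_b")
  p1 <- write_community(c1, d1); p2 <- write_community(c2, d2)
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[nm]])), unname(tools::md5sum(p2[[nm]])),
                     label = nm)
  }
  # and round-trip through the readers
  expect_identical(read_fasta_alignment(p1[["fasta"]]), c1$seqs)
  expect_identical(read_counts_tsv(p1[["counts"]]), c1$counts)
})
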