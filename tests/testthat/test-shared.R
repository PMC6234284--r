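# Shared-taxon reports, group filters, accumulation curves, enrichment.

shared_fixture <- function() {
  taxa <- c("t1", "t2", "t3", "t4", "t5")
  samples <- c("M1", "M2", "F1", "F2")
  counts <- matrix(0L, 5, 4, dimnames = list(taxa, samples))
  counts["t1", ] <- c(10L, 5L, 0L, 0L)   # marine only
  counts["t2", ] <- c(1L, 0L, 1L, 0L)    # shared (single reads suffice)
  counts["t3", ] <- c(0L, 0L, 8L, 2L)    # freshwater only
  counts["t4", ] <- c(3L, 1L, 0L, 9L)    # shared
  counts["t5", ] <- c(0L, 0L, 0L, 4L)    # freshwater only
  metadata <- data.frame(sample_id = samples,
                         habitat = c("marine", "marine", "freshwater", "freshwater"),
                         site = c("sA", "sB", "sC", "sD"),
                         stringsAsFactors = FALSE)
  lineage <- data.frame(
    taxon_id = taxa,
    lineage = c("P1;C1;O1;F1;G1", "P1;C1;O1;F1;G1", "P1;C1;O1;F2;G2",
                "P2;C2;O2;F3;G3", "P2;C2;O2;F3;G4"),
    stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata, lineage = lineage)
}

test_that("shared taxa are exactly those observed in both habitats", {
  fx <- shared_fixture()
  rep <- find_shared_taxa(fx$counts, fx$metadata, fx$lineage, rank = "phylum")
  expect_setequal(rep$shared_taxa, c("t2", "t4"))
  expect_equal(rep$n_shared, 2L)
  bg <- rep$by_group
  expect_equal(bg$n_shared[bg$group == "P1"], 1L)
  expect_equal(bg$n_marine_total[bg$group == "P1"], 2L)      # t1, t2
  expect_equal(bg$n_freshwater_total[bg$group == "P1"], 2L)  # t2, t3
  expect_equal(bg$shared_frac_marine[bg$group == "P1"], 0.5)
  # one genus (G1 has t2 only shared): no genus reaches 2 shared taxa
  expect_equal(rep$genus_tally, 0L)

  expect_error(find_shared_taxa(fx$counts[, 1:3], fx$metadata[1:2, ]), "missing sample")

  # generator truth: with immigrant weight 0 nothing is shared
  comm <- simulate_community(test_spec(immigrant_weight = 0))
  rep0 <- find_shared_taxa(comm$counts, comm$metadata)
  expect_length(rep0$shared_taxa, 0)

  # and shared taxa always match a direct two-habitat presence check
  comm1 <- simulate_community(test_spec(immigrant_weight = 2e-3, seed = 8,
                                        library_size_range = c(20000L, 20000L)))
  rep1 <- find_shared_taxa(comm1$counts, comm1$metadata)
  hab <- setNames(comm1$metadata$habitat, comm1$metadata$sample_id)
  manual <- rownames(comm1$counts)[
    apply(comm1$counts[, hab == "marine"] > 0, 1, any) &
      apply(comm1$counts[, hab == "freshwater"] > 0, 1, any)]
  expect_setequal(rep1$shared_taxa, manual)
  expect_gt(length(manual), 0)  # immigrants land above the detection limit here
})

test_that("group filters enforce sample, taxon and read thresholds", {
  taxa <- sprintf("t%d", 1:12)
  samples <- c(sprintf("M%d", 1:3), sprintf("F%d", 1:3))
  counts <- matrix(0L, 12, 6, dimnames = list(taxa, samples))
  # group A (t1..t6): >=500 reads in all six samples
  counts[1:6, ] <- 200L
  # group B (t7..t12): >=500 reads in marine, only 2 freshwater samples
  counts[7:12, 1:3] <- 150L
  counts[7:12, 4:5] <- 150L
  lineage <- data.frame(taxon_id = taxa,
                        lineage = c(rep("PA;CA;OA;FA;GA", 6), rep("PB;CB;OB;FB;GB", 6)),
                        stringsAsFactors = FALSE)
  metadata <- data.frame(sample_id = samples,
                         habitat = rep(c("marine", "freshwater"), each = 3),
                         stringsAsFactors = FALSE)
  flt <- filter_groups(counts, lineage, metadata, rank = "phylum")
  expect_true(flt$groups$retained[flt$groups$group == "PA"])
  expect_false(flt$groups$retained[flt$groups$group == "PB"])

  # a sample at 499 reads is excluded for that group only
  counts2 <- counts
  counts2[1:6, "M1"] <- c(499L, 0L, 0L, 0L, 0L, 0L)
  flt2 <- filter_groups(counts2, lineage, metadata, rank = "phylum")
  excl <- flt2$excluded_samples
  expect_true(any(excl$group == "PA" & excl$sample_id == "M1"))
  expect_false(any(excl$group == "PB" & excl$sample_id == "M1"))
  # PA now has only 2 qualifying marine samples -> dropped
  expect_false(flt2$groups$retained[flt2$groups$group == "PA"])

  expect_error(filter_groups(counts, lineage, metadata, rank = "kingdom"), "unknown rank")
})

test_that("accumulation curves enumerate orderings exactly on small fixtures", {
  taxa <- c("a", "b", "c", "d")
  counts <- matrix(0L, 4, 3, dimnames = list(taxa, c("F1", "F2", "M1")))
  counts[c("a", "b"), "F1"] <- 1L
  counts[c("b", "c"), "F2"] <- 1L
  counts[c("b", "c", "d"), "M1"] <- 1L
  metadata <- data.frame(sample_id = c("F1", "F2", "M1"),
                         habitat = c("freshwater", "freshwater", "marine"),
                         site = c("sF1", "sF2", "sM1"), stringsAsFactors = FALSE)
  acc <- accumulation_curve(counts, metadata, axis_habitat = "freshwater",
                            n_orderings = 2)
  # two orderings: (F1,F2) -> 1 then 2 shared; (F2,F1) -> 2 then 2
  expect_equal(acc$mean_shared, c(1.5, 2))
  expect_equal(acc$min_shared, c(1, 2))
  expect_equal(acc$max_shared, c(2, 2))
  # final point agrees with the shared-taxon report
  rep <- find_shared_taxa(counts, metadata)
  expect_equal(acc$mean_shared[nrow(acc)], rep$n_shared)
  # fraction axis: 3 freshwater taxa in total
  expect_equal(acc$mean_frac, acc$mean_shared / 3)

  # single axis site: curve of length 1 equal to the full shared count
  acc1 <- accumulation_curve(counts, metadata, axis_habitat = "marine",
                             n_orderings = 5)
  expect_equal(nrow(acc1), 1L)
  expect_equal(acc1$mean_shared, rep$n_shared)

  expect_error(accumulation_curve(counts, metadata, n_orderings = 0), "n_orderings")

  # mean curve is non-decreasing on random communities
  comm <- simulate_community(test_spec(immigrant_weight = 2e-3, seed = 19,
                                       n_marine_samples = 5, n_freshwater_samples = 5,
                                       library_size_range = c(5000L, 5000L)))
  acc2 <- accumulation_curve(comm$counts, comm$metadata, axis_habitat = "freshwater",
                             n_orderings = 30, seed = 2)
  expect_true(all(diff(acc2$mean_shared) >= -1e-9))
  rep2 <- find_shared_taxa(comm$counts, comm$metadata)
  expect_equal(acc2$mean_shared[nrow(acc2)], rep2$n_shared)
})

test_that("fold enrichment reports log10 median ratios with habitat antisymmetry", {
  taxa <- c("g1", "filler")
  samples <- c("M1", "M2", "F1", "F2")
  counts <- matrix(0L, 2, 4, dimnames = list(taxa, samples))
  counts["g1", ] <- c(2L, 2L, 20L, 20L)       # rel 0.002 marine, 0.02 freshwater
  counts["filler", ] <- c(998L, 998L, 980L, 980L)
  metadata <- data.frame(sample_id = samples,
                         habitat = c("marine", "marine", "freshwater", "freshwater"),
                         stringsAsFactors = FALSE)
  lineage <- data.frame(taxon_id = taxa,
                        lineage = c("PG;CG;OG;FG;GG", "PF;CF;OF;FF;GF"),
                        stringsAsFactors = FALSE)
  fe <- fold_enrichment(counts, lineage, metadata, rank = "phylum")
  expect_equal(fe$log10_fold_change[fe$group == "PG"], 1.0)
  expect_false(any(fe$pseudo_used))

  # equal medians give 0
  counts_eq <- counts
  counts_eq["g1", ] <- c(10L, 10L, 10L, 10L)
  counts_eq["filler", ] <- c(990L, 990L, 990L, 990L)
  fe_eq <- fold_enrichment(counts_eq, lineage, metadata, rank = "phylum")
  expect_equal(fe_eq$log10_fold_change, c(0, 0))

  # antisymmetry under habitat swap when no pseudo-abundance triggers
  metadata_sw <- metadata
  metadata_sw$habitat <- rev(metadata$habitat)
  fe_sw <- fold_enrichment(counts, lineage, metadata_sw, rank = "phylum")
  expect_equal(fe_sw$log10_fold_change, -fe$log10_fold_change)
})
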