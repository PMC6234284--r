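## Per-edge descendant-tip incidence via one postorder pass; the branch
## bookkeeping both UniFrac variants share.
edge_tip_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- stats::reorder(tree, "postorder")
  ne <- nrow(po$edge)
  M <- matrix(FALSE, ne, ntip, dimnames = list(NULL, tree$tip.label))
  nodeset <- matrix(FALSE, ntip + tree$Nnode, ntip)
  nodeset[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (k in seq_len(ne)) {
    ch <- po$edge[k, 2]; pa <- po$edge[k, 1]
    M[k, ] <- nodeset[ch, ]
    nodeset[pa, ] <- nodeset[pa, ] | nodeset[ch, ]
  }
  list(incidence = M, lengths = po$edge.length)
}

check_tips <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0L)
    stop(sprintf("taxa not present as tree tips: %s", paste(utils::head(missing, 5), collapse = ", ")))
}

#' Unweighted UniFrac distance
#'
#' Fraction of the tree's branch length leading exclusively to tips of one
#' of the two assemblages, out of the branch length leading to tips of
#' either. Equals 0 for identical presence sets and exactly 1 when the two
#' assemblages share no branch — i.e. when they occupy phylogenetically
#' completely distinct subtrees.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param presence_a,presence_b character vectors of tip labels present in
#'   each assemblage.
#' @return distance in `[0, 1]`.
#' @export
unweighted_unifrac <- function(tree, presence_a, presence_b) {
  presence_a <- unique(presence_a); presence_b <- unique(presence_b)
  if (length(presence_a) == 0L || length(presence_b) == 0L)
    stop("both presence sets must be non-empty")
  check_tips(tree, c(presence_a, presence_b))
  et <- edge_tip_matrix(tree)
  in_a <- rowSums(et$incidence[, presence_a, drop = FALSE]) > 0
  in_b <- rowSums(et$incidence[, presence_b, drop = FALSE]) > 0
  union_len <- sum(et$lengths[in_a | in_b])
  if (union_len == 0) return(0)
  sum(et$lengths[xor(in_a, in_b)]) / union_len
}

#' Weighted UniFrac distance (normalized)
#'
#' Branch-proportion form: `sum(b * |pA - pB|) / sum(b * (pA + pB))`,
#' where `pX` is the fraction of assemblage X's total abundance descending
#' through each branch. Lies in `[0, 1]`, equals 0 for identical relative
#' abundance profiles and 1 when the supported tip sets share no branch.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param counts_a,counts_b named non-negative numeric vectors of tip
#'   abundances (tips absent from a vector count as zero).
#' @return distance in `[0, 1]`.
#' @export
weighted_unifrac <- function(tree, counts_a, counts_b) {
  if (is.null(names(counts_a)) || is.null(names(counts_b)))
    stop("count vectors must be named by tip label")
  if (sum(counts_a) <= 0 || sum(counts_b) <= 0)
    stop("both samples must have positive total abundance")
  check_tips(tree, c(names(counts_a)[counts_a > 0], names(counts_b)[counts_b > 0]))
  et <- edge_tip_matrix(tree)
  tips <- colnames(et$incidence)
  va <- stats::setNames(numeric(length(tips)), tips)
  vb <- va
  va[names(counts_a)[names(counts_a) %in% tips]] <- counts_a[names(counts_a) %in% tips]
  vb[names(counts_b)[names(counts_b) %in% tips]] <- counts_b[names(counts_b) %in% tips]
  pa <- as.vector(et$incidence %*% va) / sum(va)
  pb <- as.vector(et$incidence %*% vb) / sum(vb)
  denom <- sum(et$lengths * (pa + pb))
  if (denom == 0) return(0)
  sum(et$lengths * abs(pa - pb)) / denom
}

#' Rarefy a count table to even depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads;
#' samples whose total falls below `depth` are dropped with a warning.
#'
#' @param counts integer taxon-by-sample matrix.
#' @param depth target reads per sample (> 0).
#' @param seed integer seed making the subsampling reproducible.
#' @return rarefied taxon-by-sample matrix (possibly fewer columns).
#' @export
rarefy <- function(counts, depth, seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  totals <- colSums(counts)
  drop <- totals < depth
  if (any(drop)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(drop), depth, paste(colnames(counts)[drop], collapse = ", ")))
    counts <- counts[, !drop, drop = FALSE]
  }
  if (ncol(counts) == 0L) return(counts)
  set.seed(seed)
  out <- withCallingHandlers(
    t(vegan::rrarefy(t(counts), depth)),
    # vegan nags when the smallest nonzero count exceeds 1; our inputs are
    # genuine counts, so the reminder is noise
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "integer"
  out
}

#' Pooled-habitat UniFrac per taxonomic group
#'
#' For every group passing the inclusion filter (see [filter_groups()]),
#' all marine samples are pooled into one assemblage and all freshwater
#' samples into another, the group's subtree is extracted, and the
#' unweighted UniFrac distance between the pooled assemblages is computed.
#' Per-sample pairwise distances within the group are summarized alongside
#' (median and range over all marine-freshwater pairs).
#'
#' @param tree rooted `phylo` over all taxa.
#' @param counts taxon-by-sample count matrix.
#' @param metadata data frame with `sample_id` and `habitat`.
#' @param lineage lineage data frame.
#' @param rank taxonomic rank defining groups.
#' @param min_samples,min_taxa,min_group_reads passed to [filter_groups()].
#' @return data frame: group, pooled UniFrac, pairwise median/min/max,
#'   number of taxa, evaluable flag.
#' @export
pooled_group_unifrac <- function(tree, counts, metadata, lineage, rank = "family",
                                 min_samples = 3L, min_taxa = 5L, min_group_reads = 500L) {
  flt <- filter_groups(counts, lineage, metadata, rank,
                       min_samples = min_samples, min_taxa = min_taxa,
                       min_group_reads = min_group_reads)
  grp <- lineage_at_rank(lineage, rank)
  marine <- intersect(metadata$sample_id[metadata$habitat == "marine"], colnames(counts))
  fresh <- intersect(metadata$sample_id[metadata$habitat == "freshwater"], colnames(counts))

  rows <- lapply(flt$groups$group[flt$groups$retained], function(g) {
    taxa <- intersect(names(grp)[grp == g], intersect(rownames(counts), tree$tip.label))
    excl <- flt$excluded_samples$sample_id[flt$excluded_samples$group == g]
    m_use <- setdiff(marine, excl)
    f_use <- setdiff(fresh, excl)
    sub <- counts[taxa, , drop = FALSE]
    pool_m <- taxa[rowSums(sub[, m_use, drop = FALSE]) > 0]
    pool_f <- taxa[rowSums(sub[, f_use, drop = FALSE]) > 0]
    if (length(pool_m) == 0L || length(pool_f) == 0L)
      return(data.frame(group = g, pooled_unifrac = NA_real_, pair_median = NA_real_,
                        pair_min = NA_real_, pair_max = NA_real_,
                        n_taxa = length(taxa), evaluable = FALSE))
    subtree <- ape::keep.tip(tree, taxa)
    pooled <- unweighted_unifrac(subtree, pool_m, pool_f)
    pairs <- numeric(0)
    for (ms in m_use) for (fs in f_use) {
      pa <- taxa[sub[, ms] > 0]; pb <- taxa[sub[, fs] > 0]
      if (length(pa) > 0L && length(pb) > 0L)
        pairs <- c(pairs, unweighted_unifrac(subtree, pa, pb))
    }
    data.frame(group = g, pooled_unifrac = pooled,
               pair_median = if (length(pairs)) stats::median(pairs) else NA_real_,
               pair_min = if (length(pairs)) min(pairs) else NA_real_,
               pair_max = if (length(pairs)) max(pairs) else NA_real_,
               n_taxa = length(taxa), evaluable = TRUE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(0), pooled_unifrac = numeric(0),
                      pair_median = numeric(0), pair_min = numeric(0),
                      pair_max = numeric(0), n_taxa = integer(0), evaluable = logical(0))
  rownames(out) <- NULL
  out
}

#' Swap-null z tests for habitat grouping, per taxonomic group
#'
#' For each retained group, the observed pooled-habitat unweighted UniFrac
#' is compared against a null ensemble built by independent-swap
#' randomization of the group's presence-absence taxon-by-sample matrix:
#' each randomized matrix is re-pooled by habitat and the statistic
#' recomputed. One-sample z tests (upper tail) with a Bonferroni
#' correction across groups quantify whether the tree is grouped by
#' habitat more than margins alone explain.
#'
#' @inheritParams pooled_group_unifrac
#' @param n_rand number of swap randomizations (default 1000).
#' @param seed integer seed.
#' @return data frame: group, observed, null mean/sd, z, p, p_bonferroni.
#' @export
group_unifrac_ztests <- function(tree, counts, metadata, lineage, rank = "phylum",
                                 n_rand = 1000L, seed = 1L,
                                 min_samples = 3L, min_taxa = 5L, min_group_reads = 500L) {
  flt <- filter_groups(counts, lineage, metadata, rank,
                       min_samples = min_samples, min_taxa = min_taxa,
                       min_group_reads = min_group_reads)
  groups <- flt$groups$group[flt$groups$retained]
  grp <- lineage_at_rank(lineage, rank)
  habitat <- stats::setNames(metadata$habitat, metadata$sample_id)

  rows <- lapply(seq_along(groups), function(gi) {
    g <- groups[gi]
    taxa <- intersect(names(grp)[grp == g], intersect(rownames(counts), tree$tip.label))
    excl <- flt$excluded_samples$sample_id[flt$excluded_samples$group == g]
    use <- setdiff(intersect(metadata$sample_id, colnames(counts)), excl)
    pres <- (counts[taxa, use, drop = FALSE] > 0) * 1L
    subtree <- ape::keep.tip(tree, taxa)
    pool <- function(m) {
      pm <- rownames(m)[rowSums(m[, habitat[colnames(m)] == "marine", drop = FALSE]) > 0]
      pf <- rownames(m)[rowSums(m[, habitat[colnames(m)] == "freshwater", drop = FALSE]) > 0]
      if (length(pm) == 0L || length(pf) == 0L) return(NA_real_)
      unweighted_unifrac(subtree, pm, pf)
    }
    obs <- pool(pres)
    draws <- independent_swap_null(pres, n_rand = n_rand, seed = seed + gi)
    nulls <- vapply(draws, pool, numeric(1))
    nulls <- nulls[!is.na(nulls)]
    zt <- z_test(obs, nulls, n_groups = length(groups))
    data.frame(group = g, observed = obs, null_mean = zt$mean_null,
               null_sd = zt$sd_null, z = zt$z, p = zt$p,
               p_bonferroni = zt$p_bonferroni)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(0), observed = numeric(0), null_mean = numeric(0),
                      null_sd = numeric(0), z = numeric(0), p = numeric(0),
                      p_bonferroni = numeric(0))
  rownames(out) <- NULL
  out
}

#' Sample-by-sample UniFrac distance matrix
#'
#' @param tree rooted `phylo`.
#' @param counts taxon-by-sample count matrix.
#' @param weighted compute the weighted variant (default unweighted).
#' @return symmetric sample-by-sample distance matrix.
#' @export
unifrac_matrix <- function(tree, counts, weighted = FALSE) {
  samples <- colnames(counts)
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  taxa <- intersect(rownames(counts), tree$tip.label)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (weighted) {
      d[i, j] <- d[j, i] <- weighted_unifrac(tree,
        stats::setNames(counts[taxa, i], taxa), stats::setNames(counts[taxa, j], taxa))
    } else {
      pa <- taxa[counts[taxa, i] > 0]; pb <- taxa[counts[taxa, j] > 0]
      d[i, j] <- d[j, i] <- unweighted_unifrac(tree, pa, pb)
    }
  }
  d
}
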