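#' Jaccard distance between two taxon sets
#'
#' One minus the number of shared units divided by the total number of
#' units across both samples; a value of 1 means no taxa are shared.
#'
#' @param sample_a,sample_b vectors of taxon (or cluster) ids.
#' @return Jaccard distance in `[0, 1]`.
#' @export
jaccard_distance <- function(sample_a, sample_b) {
  a <- unique(sample_a)
  b <- unique(sample_b)
  if (length(a) == 0L && length(b) == 0L)
    stop("Jaccard distance is undefined for two empty samples")
  1 - length(intersect(a, b)) / length(union(a, b))
}

#' Highest shared-identity threshold for one marine-freshwater sample pair
#'
#' Walks the clustering cutoff grid from finest (100% identity) to
#' coarsest and returns `identity = 1 - cutoff` at the first cutoff where
#' some cluster contains at least one sequence observed in the marine
#' sample and one observed in the freshwater sample — equivalently, the
#' largest identity at which the pair's cluster-level Jaccard distance
#' drops below 1. A value of 1.0 means the two habitats share an identical
#' sequence; low values indicate anciently split, habitat-exclusive
#' clades. The statistic is symmetric in its two samples.
#'
#' @param clust a `multithreshold_clustering` over the group's sequences.
#' @param counts taxon-by-sample count matrix (rows must cover the
#'   clustered sequence ids).
#' @param marine_id,freshwater_id sample column names.
#' @return the maximum shared identity, a value on the grid `1 - cutoffs`.
#' @export
pair_scan <- function(clust, counts, marine_id, freshwater_id) {
  stopifnot(inherits(clust, "multithreshold_clustering"))
  for (s in c(marine_id, freshwater_id))
    if (!s %in% colnames(counts)) stop(sprintf("sample '%s' absent from count table", s))
  ids <- intersect(clust$ids, rownames(counts))
  pres_a <- ids[counts[ids, marine_id] > 0]
  pres_b <- ids[counts[ids, freshwater_id] > 0]
  if (length(pres_a) == 0L)
    stop(sprintf("sample '%s' has no sequences in this group", marine_id))
  if (length(pres_b) == 0L)
    stop(sprintf("sample '%s' has no sequences in this group", freshwater_id))
  memb <- clust$membership
  for (ci in seq_along(clust$cutoffs)) {
    if (length(intersect(unique(memb[pres_a, ci]), unique(memb[pres_b, ci]))) > 0L)
      return(1 - clust$cutoffs[ci])
  }
  ## unreachable for a full grid (single cluster at the collapse cutoff),
  ## but keep the contract explicit
  1 - clust$collapse
}

#' Shared-identity scan over all marine-freshwater pairs, per group
#'
#' For each taxonomic group at `rank`, sequences are clustered
#' independently and every marine-freshwater sample pair is scanned for
#' its highest shared-identity threshold. Pairs where either sample lacks
#' the group are skipped and counted rather than silently dropped. Samples
#' are used unrarefied.
#'
#' @param seqs aligned character matrix over all sequences.
#' @param counts taxon-by-sample count matrix (rows = sequence/taxon ids).
#' @param metadata data frame with `sample_id` and `habitat`.
#' @param lineage lineage data frame (see [read_lineage_tsv()]).
#' @param rank taxonomic rank defining the groups (default `"phylum"`).
#' @param grid_step clustering grid step (default 0.001).
#' @return list of `scan_result` lists, one per group: `group`,
#'   `evaluable`, `pairs` (data frame marine_id / freshwater_id /
#'   max_shared_identity), `n_pairs_skipped`, `n_marine_present`,
#'   `n_freshwater_present`, and `summary` (median, quartiles, range).
#' @export
group_scan <- function(seqs, counts, metadata, lineage, rank = "phylum",
                       grid_step = 0.001) {
  grp <- lineage_at_rank(lineage, rank)
  marine <- metadata$sample_id[metadata$habitat == "marine"]
  fresh <- metadata$sample_id[metadata$habitat == "freshwater"]
  marine <- intersect(marine, colnames(counts))
  fresh <- intersect(fresh, colnames(counts))

  out <- list()
  for (g in sort(unique(grp))) {
    taxa <- names(grp)[grp == g]
    taxa <- intersect(taxa, intersect(rownames(seqs), rownames(counts)))
    res <- list(group = g, evaluable = TRUE, pairs = NULL, n_pairs_skipped = 0L,
                n_marine_present = 0L, n_freshwater_present = 0L, summary = NULL)
    if (length(taxa) == 0L) {
      res$evaluable <- FALSE
      out[[g]] <- structure(res, class = "scan_result")
      next
    }
    sub <- counts[taxa, , drop = FALSE]
    m_present <- marine[colSums(sub[, marine, drop = FALSE]) > 0]
    f_present <- fresh[colSums(sub[, fresh, drop = FALSE]) > 0]
    res$n_marine_present <- length(m_present)
    res$n_freshwater_present <- length(f_present)
    if (length(m_present) < 1L || length(f_present) < 1L) {
      res$evaluable <- FALSE
      out[[g]] <- structure(res, class = "scan_result")
      next
    }
    clust <- if (length(taxa) >= 2L) {
      farthest_neighbor_cluster(pairwise_distance(seqs[taxa, , drop = FALSE]), grid_step)
    } else {
      structure(list(cutoffs = 0, membership = matrix(1L, 1, 1, dimnames = list(taxa, NULL)),
                     merges = data.frame(height = numeric(0), rep_a = integer(0), rep_b = integer(0)),
                     ids = taxa, collapse = 0),
                class = "multithreshold_clustering")
    }
    grid_pairs <- expand.grid(marine_id = marine, freshwater_id = fresh,
                              stringsAsFactors = FALSE)
    keep <- grid_pairs$marine_id %in% m_present & grid_pairs$freshwater_id %in% f_present
    res$n_pairs_skipped <- sum(!keep)
    grid_pairs <- grid_pairs[keep, , drop = FALSE]
    grid_pairs$max_shared_identity <- vapply(seq_len(nrow(grid_pairs)), function(k) {
      pair_scan(clust, sub, grid_pairs$marine_id[k], grid_pairs$freshwater_id[k])
    }, numeric(1))
    res$pairs <- grid_pairs
    v <- grid_pairs$max_shared_identity
    res$summary <- c(median = stats::median(v),
                     q1 = unname(stats::quantile(v, 0.25)),
                     q3 = unname(stats::quantile(v, 0.75)),
                     min = min(v), max = max(v))
    out[[g]] <- structure(res, class = "scan_result")
  }
  out
}

#' Tidy the output of [group_scan()]
#'
#' @param scan list returned by [group_scan()].
#' @return list of two data frames: `pairs` (long, one row per evaluated
#'   sample pair) and `summary` (one row per group).
#' @export
scan_tables <- function(scan) {
  pairs <- do.call(rbind, lapply(scan, function(r) {
    if (is.null(r$pairs) || nrow(r$pairs) == 0L) return(NULL)
    cbind(group = r$group, r$pairs, stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(scan, function(r) {
    data.frame(group = r$group, evaluable = r$evaluable,
               n_marine_present = r$n_marine_present,
               n_freshwater_present = r$n_freshwater_present,
               n_pairs_skipped = r$n_pairs_skipped,
               median = if (is.null(r$summary)) NA_real_ else r$summary[["median"]],
               q1 = if (is.null(r$summary)) NA_real_ else r$summary[["q1"]],
               q3 = if (is.null(r$summary)) NA_real_ else r$summary[["q3"]],
               min = if (is.null(r$summary)) NA_real_ else r$summary[["min"]],
               max = if (is.null(r$summary)) NA_real_ else r$summary[["max"]],
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  if (!is.null(pairs)) rownames(pairs) <- NULL
  list(pairs = pairs, summary = summary)
}
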