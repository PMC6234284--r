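#' Identify taxa shared between marine and freshwater samples
#'
#' A taxon is shared when it is observed (count > 0) in at least one
#' marine and at least one freshwater sample of the unrarefied count
#' table. When a lineage table is supplied, per-group shared counts,
#' per-habitat totals and shared fractions are reported, along with a
#' genus-level tally of genera containing at least two shared taxa.
#'
#' @param counts unrarefied taxon-by-sample count matrix.
#' @param metadata data frame with `sample_id` and `habitat` covering
#'   every count column.
#' @param lineage optional lineage data frame.
#' @param rank rank for the per-group breakdown (default `"phylum"`).
#' @return list of class `shared_taxon_report`: `shared_taxa` (ids),
#'   `n_shared`, `by_group` (data frame or NULL), `genus_tally` (number
#'   of genera with >= 2 shared taxa, or NA without lineage).
#' @export
find_shared_taxa <- function(counts, metadata, lineage = NULL, rank = "phylum") {
  missing <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing) > 0L)
    stop(sprintf("metadata missing sample(s): %s", paste(missing, collapse = ", ")))
  habitat <- stats::setNames(metadata$habitat, metadata$sample_id)[colnames(counts)]
  in_marine <- rowSums(counts[, habitat == "marine", drop = FALSE] > 0) > 0
  in_fresh <- rowSums(counts[, habitat == "freshwater", drop = FALSE] > 0) > 0
  shared <- rownames(counts)[in_marine & in_fresh]

  by_group <- NULL
  genus_tally <- NA_integer_
  if (!is.null(lineage)) {
    grp <- lineage_at_rank(lineage, rank)[rownames(counts)]
    by_group <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
      taxa <- rownames(counts)[grp == g & !is.na(grp)]
      n_m <- sum(in_marine[taxa]); n_f <- sum(in_fresh[taxa])
      n_sh <- sum(taxa %in% shared)
      data.frame(group = g, n_shared = n_sh,
                 n_marine_total = n_m, n_freshwater_total = n_f,
                 shared_frac_marine = if (n_m > 0) n_sh / n_m else NA_real_,
                 shared_frac_freshwater = if (n_f > 0) n_sh / n_f else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    rownames(by_group) <- NULL
    gen <- lineage_at_rank(lineage, "genus")[rownames(counts)]
    tab <- table(gen[rownames(counts) %in% shared])
    genus_tally <- sum(tab >= 2L)
  }
  structure(list(shared_taxa = shared, n_shared = length(shared),
                 by_group = by_group, genus_tally = genus_tally),
            class = "shared_taxon_report")
}

#' Apply the group inclusion filter
#'
#' A group at `rank` is retained when it is present in at least
#' `min_samples` samples of each habitat and contains at least `min_taxa`
#' taxa. A sample contributing fewer than `min_group_reads` reads of a
#' group is excluded from that group's analyses only (and does not count
#' toward presence).
#'
#' @param counts taxon-by-sample count matrix.
#' @param lineage lineage data frame.
#' @param metadata data frame with `sample_id` and `habitat`.
#' @param rank taxonomic rank defining groups.
#' @param min_samples minimum samples per habitat (default 3).
#' @param min_taxa minimum taxa per group (default 5).
#' @param min_group_reads minimum group reads for a sample to count
#'   (default 500).
#' @return list: `groups` (data frame with per-habitat presence counts,
#'   taxon counts, retained flag) and `excluded_samples` (data frame
#'   group / sample_id / total).
#' @export
filter_groups <- function(counts, lineage, metadata, rank = "phylum",
                          min_samples = 3L, min_taxa = 5L, min_group_reads = 500L) {
  grp <- lineage_at_rank(lineage, rank)
  habitat <- stats::setNames(metadata$habitat, metadata$sample_id)
  samples <- intersect(colnames(counts), metadata$sample_id)

  groups <- sort(unique(grp[rownames(counts)]))
  rows <- list(); excl <- list()
  for (g in groups) {
    taxa <- intersect(names(grp)[grp == g], rownames(counts))
    totals <- colSums(counts[taxa, samples, drop = FALSE])
    low <- totals > 0 & totals < min_group_reads
    if (any(low))
      excl[[g]] <- data.frame(group = g, sample_id = samples[low],
                              total = unname(totals[low]), stringsAsFactors = FALSE)
    present <- samples[totals >= min_group_reads]
    n_m <- sum(habitat[present] == "marine")
    n_f <- sum(habitat[present] == "freshwater")
    n_taxa <- sum(rowSums(counts[taxa, present, drop = FALSE]) > 0)
    rows[[g]] <- data.frame(group = g, n_marine = n_m, n_freshwater = n_f,
                            n_taxa = n_taxa,
                            retained = n_m >= min_samples && n_f >= min_samples &&
                              n_taxa >= min_taxa,
                            stringsAsFactors = FALSE)
  }
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(group = character(0), sample_id = character(0), total = numeric(0))
  groups_df <- do.call(rbind, rows)
  rownames(groups_df) <- rownames(excluded) <- NULL
  list(groups = groups_df, excluded_samples = excluded)
}

## all permutations of a vector (used for exact accumulation curves)
all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

#' Shared-taxon accumulation curve over sampling sites
#'
#' Holds the full site set of the opposite habitat fixed and adds sites of
#' `axis_habitat` in random order; after each addition the number of taxa
#' shared with the opposite-habitat pool is recorded, along with the
#' fraction of the axis habitat's taxa that are shared. Curves are
#' averaged over orderings (all distinct orderings are enumerated when
#' there are no more of them than `n_orderings`; otherwise `n_orderings`
#' random orderings are drawn).
#'
#' @param counts unrarefied taxon-by-sample count matrix.
#' @param metadata data frame with `sample_id`, `habitat` and `site`.
#' @param lineage optional lineage data frame restricting taxa to `group`.
#' @param group optional group label at `rank` to restrict the curve to.
#' @param rank rank of `group` (default `"phylum"`).
#' @param axis_habitat habitat whose sites are accumulated.
#' @param n_orderings orderings to average over (default 100).
#' @param seed integer seed.
#' @return data frame: `n_sites`, `mean_shared`, `min_shared`,
#'   `max_shared`, `mean_frac`, `min_frac`, `max_frac`.
#' @export
accumulation_curve <- function(counts, metadata, lineage = NULL, group = NULL,
                               rank = "phylum", axis_habitat = "freshwater",
                               n_orderings = 100L, seed = 1L) {
  if (n_orderings < 1L) stop("n_orderings must be >= 1")
  if (!axis_habitat %in% c("marine", "freshwater"))
    stop("axis_habitat must be 'marine' or 'freshwater'")
  taxa <- rownames(counts)
  if (!is.null(group)) {
    if (is.null(lineage)) stop("a lineage table is required to restrict to a group")
    grp <- lineage_at_rank(lineage, rank)
    taxa <- intersect(names(grp)[grp == group], taxa)
    if (length(taxa) == 0L) stop(sprintf("no taxa in group '%s'", group))
  }
  sub <- counts[taxa, , drop = FALSE]
  other <- setdiff(c("marine", "freshwater"), axis_habitat)
  meta <- metadata[metadata$sample_id %in% colnames(sub), ]
  axis_meta <- meta[meta$habitat == axis_habitat, ]
  other_samples <- meta$sample_id[meta$habitat == other]
  sites <- unique(axis_meta$site)
  if (length(sites) < 1L || length(other_samples) < 1L)
    stop("need at least one site on each habitat axis")

  other_pool <- taxa[rowSums(sub[, other_samples, drop = FALSE]) > 0]
  axis_total <- sum(rowSums(sub[, axis_meta$sample_id, drop = FALSE]) > 0)
  site_taxa <- lapply(sites, function(s) {
    ss <- axis_meta$sample_id[axis_meta$site == s]
    taxa[rowSums(sub[, ss, drop = FALSE]) > 0]
  })
  names(site_taxa) <- sites

  S <- length(sites)
  n_all <- factorial(S)
  orderings <- if (n_all <= n_orderings) {
    all_permutations(sites)
  } else {
    set.seed(seed)
    lapply(seq_len(n_orderings), function(i) sample(sites))
  }

  shared_mat <- matrix(0, length(orderings), S)
  for (o in seq_along(orderings)) {
    cum <- character(0)
    for (j in seq_len(S)) {
      cum <- union(cum, site_taxa[[orderings[[o]][j]]])
      shared_mat[o, j] <- length(intersect(cum, other_pool))
    }
  }
  data.frame(
    n_sites = seq_len(S),
    mean_shared = colMeans(shared_mat),
    min_shared = apply(shared_mat, 2, min),
    max_shared = apply(shared_mat, 2, max),
    mean_frac = colMeans(shared_mat) / axis_total,
    min_frac = apply(shared_mat, 2, min) / axis_total,
    max_frac = apply(shared_mat, 2, max) / axis_total
  )
}

#' Habitat fold-enrichment per taxonomic group
#'
#' For every group at `rank`, the median relative abundance across
#' freshwater samples and across marine samples, and
#' `log10(median_freshwater / median_marine)`. A log10 fold change of 0
#' means the habitats' medians are equal; +/-1 corresponds to a tenfold
#' enrichment in one habitat. A zero median is replaced by a
#' pseudo-abundance equal to half the smallest nonzero per-sample group
#' relative abundance observed in the call.
#'
#' @param counts taxon-by-sample count matrix.
#' @param lineage lineage data frame.
#' @param metadata data frame with `sample_id` and `habitat`.
#' @param rank taxonomic rank defining groups.
#' @return data frame: group, median_freshwater, median_marine,
#'   log10_fold_change, pseudo_used.
#' @export
fold_enrichment <- function(counts, lineage, metadata, rank = "phylum") {
  grp <- lineage_at_rank(lineage, rank)
  habitat <- stats::setNames(metadata$habitat, metadata$sample_id)[colnames(counts)]
  rel <- sweep(counts, 2, colSums(counts), "/")
  groups <- sort(unique(grp[rownames(counts)]))

  grp_rel <- t(vapply(groups, function(g) {
    taxa <- intersect(names(grp)[grp == g], rownames(counts))
    colSums(rel[taxa, , drop = FALSE])
  }, numeric(ncol(counts))))
  pseudo <- min(grp_rel[grp_rel > 0]) / 2

  rows <- lapply(seq_along(groups), function(i) {
    med_f <- stats::median(grp_rel[i, habitat == "freshwater"])
    med_m <- stats::median(grp_rel[i, habitat == "marine"])
    pseudo_used <- med_f == 0 || med_m == 0
    data.frame(group = groups[i],
               median_freshwater = med_f, median_marine = med_m,
               log10_fold_change = log10(max(med_f, pseudo) / max(med_m, pseudo)),
               pseudo_used = pseudo_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
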