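#' Default pipeline configuration
#'
#' Stage parameters mirror the analysis the package implements: a 0.001
#' identity-cutoff grid, rarefaction to 9,827 reads per sample, 1,000
#' independent-swap randomizations, 999 PerMANOVA permutations, and the
#' detection-model worked example (1 cell/ml in 500,000 cells/ml,
#' 150,000-read library). Every stochastic stage derives its seed from the
#' single top-level `seed`.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    stages = c("simulate", "cluster", "scan", "unifrac", "shared", "detect"),
    seed = 1L,
    inputs = NULL,  # named paths (fasta, tree, counts, metadata, lineage) when not simulating
    simulate = list(),  # overrides for synthetic_spec()
    cluster = list(grid_step = 0.001, rank = "phylum"),
    scan = list(rank = "phylum", grid_step = 0.001),
    unifrac = list(rarefaction_depth = 9827L, n_rand = 1000L, n_perm = 999L,
                   rank = "phylum", pooled_rank = "family"),
    shared = list(rank = "phylum", n_orderings = 100L),
    detect = list(pop_density = 1, community_density = 5e5,
                  library_size = 150000L, s = c(0.1, 0.001),
                  area_m2 = 5.8e10, depth_m = 1)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

write_square_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate pipeline input files
#'
#' Checks alignment-length uniformity, tree/count-table tip agreement,
#' metadata completeness and the habitat label vocabulary, and lineage
#' coverage. Reporting only: every violation found is returned, nothing
#' throws.
#'
#' @param paths named list or vector with entries `fasta`, `tree`,
#'   `counts`, `metadata`, `lineage` (any subset).
#' @return character vector of violations; empty when everything is clean.
#' @export
validate_inputs <- function(paths) {
  v <- character(0)
  note <- function(msg) v <<- c(v, msg)
  get <- function(nm) if (nm %in% names(paths) && file.exists(paths[[nm]])) paths[[nm]] else {
    if (nm %in% names(paths)) note(sprintf("%s file not found: %s", nm, paths[[nm]]))
    NULL
  }

  seqs <- NULL
  if (!is.null(p <- get("fasta"))) {
    seqs <- tryCatch(read_fasta_alignment(p), error = function(e) { note(conditionMessage(e)); NULL })
  }
  tree <- if (!is.null(p <- get("tree")))
    tryCatch(ape::read.tree(p), error = function(e) { note(sprintf("unreadable tree: %s", conditionMessage(e))); NULL })
  counts <- if (!is.null(p <- get("counts")))
    tryCatch(read_counts_tsv(p), error = function(e) { note(sprintf("unreadable counts: %s", conditionMessage(e))); NULL })
  meta <- if (!is.null(p <- get("metadata")))
    tryCatch(read_metadata_tsv(p), error = function(e) { note(sprintf("unreadable metadata: %s", conditionMessage(e))); NULL })
  lin <- if (!is.null(p <- get("lineage")))
    tryCatch(read_lineage_tsv(p), error = function(e) { note(sprintf("unreadable lineage: %s", conditionMessage(e))); NULL })

  if (!is.null(tree) && !is.null(counts)) {
    m1 <- setdiff(tree$tip.label, rownames(counts))
    if (length(m1)) note(sprintf("tree tips absent from count table: %s", paste(m1, collapse = ", ")))
    m2 <- setdiff(rownames(counts), tree$tip.label)
    if (length(m2)) note(sprintf("count-table taxa absent from tree: %s", paste(m2, collapse = ", ")))
  }
  if (!is.null(seqs) && !is.null(counts)) {
    m3 <- setdiff(rownames(counts), rownames(seqs))
    if (length(m3)) note(sprintf("count-table taxa absent from alignment: %s", paste(m3, collapse = ", ")))
  }
  if (!is.null(meta)) {
    badhab <- setdiff(unique(meta$habitat), c("marine", "freshwater"))
    if (length(badhab)) note(sprintf("unknown habitat label(s): %s", paste(badhab, collapse = ", ")))
    if (!is.null(counts)) {
      m4 <- setdiff(colnames(counts), meta$sample_id)
      if (length(m4)) note(sprintf("samples missing from metadata: %s", paste(m4, collapse = ", ")))
    }
  }
  if (!is.null(lin) && !is.null(counts)) {
    m5 <- setdiff(rownames(counts), lin$taxon_id)
    if (length(m5)) note(sprintf("taxa missing from lineage table: %s", paste(m5, collapse = ", ")))
  }
  v
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order — simulate (or load
#' inputs), multi-threshold clustering, the shared-identity scan, UniFrac
#' with PerMANOVA and swap-null z tests, shared-taxon statistics, and the
#' detection model — writing each stage's tables under `out_dir` and a
#' manifest recording parameters, seeds and the MD5 of every output, so
#' a rerun with the same configuration is byte-identical (manifests differ
#' only in their timestamp).
#'
#' @param config configuration list (merged over [default_config()]) or a
#'   path to a JSON file with the same structure.
#' @param out_dir output directory.
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- merge_config(default_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop(sprintf("output directory not writable: %s", out_dir))

  manifest <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = cfg$seed, stages = list())
  record <- function(stage, params, files) {
    md5 <- tools::md5sum(unname(files))
    # key by path relative to out_dir so manifests are location-independent
    names(md5) <- sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", out_dir), "/?"),
                      "", unname(files))
    manifest$stages[[stage]] <<- list(params = params, outputs = as.list(md5))
  }

  comm <- NULL
  if ("simulate" %in% cfg$stages) {
    spec <- do.call(synthetic_spec, merge_config(list(seed = cfg$seed), cfg$simulate))
    comm <- simulate_community(spec)
    files <- write_community(comm, file.path(out_dir, "simulate"))
    record("simulate", unclass(spec), files)
  } else {
    if (is.null(cfg$inputs)) stop("stage 'simulate' disabled and no inputs provided")
    viol <- validate_inputs(cfg$inputs)
    if (length(viol)) stop(paste(c("invalid inputs:", viol), collapse = "\n  "))
    comm <- list(
      seqs = read_fasta_alignment(cfg$inputs$fasta),
      tree = ape::read.tree(cfg$inputs$tree),
      counts = read_counts_tsv(cfg$inputs$counts),
      metadata = read_metadata_tsv(cfg$inputs$metadata),
      lineage = read_lineage_tsv(cfg$inputs$lineage)
    )
  }

  if ("cluster" %in% cfg$stages) {
    dir.create(file.path(out_dir, "cluster"), showWarnings = FALSE)
    grp <- lineage_at_rank(comm$lineage, cfg$cluster$rank)
    files <- character(0)
    for (g in sort(unique(grp))) {
      taxa <- intersect(names(grp)[grp == g], rownames(comm$seqs))
      if (length(taxa) < 2L) next
      cl <- farthest_neighbor_cluster(pairwise_distance(comm$seqs[taxa, , drop = FALSE]),
                                      cfg$cluster$grid_step)
      long <- data.frame(
        cutoff = rep(cl$cutoffs, each = length(taxa)),
        cluster_id = as.vector(cl$membership),
        sequence_id = rep(cl$ids, times = length(cl$cutoffs))
      )
      f <- file.path(out_dir, "cluster", sprintf("clusters_%s.tsv", g))
      utils::write.table(long, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
    record("cluster", cfg$cluster, files)
  }

  if ("scan" %in% cfg$stages) {
    dir.create(file.path(out_dir, "scan"), showWarnings = FALSE)
    sc <- group_scan(comm$seqs, comm$counts, comm$metadata, comm$lineage,
                     rank = cfg$scan$rank, grid_step = cfg$scan$grid_step)
    tabs <- scan_tables(sc)
    f1 <- file.path(out_dir, "scan", "scan_pairs.tsv")
    f2 <- file.path(out_dir, "scan", "scan_summary.tsv")
    utils::write.table(tabs$pairs, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tabs$summary, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    record("scan", cfg$scan, c(f1, f2))
  }

  if ("unifrac" %in% cfg$stages) {
    dir.create(file.path(out_dir, "unifrac"), showWarnings = FALSE)
    rare <- suppressWarnings(rarefy(comm$counts, cfg$unifrac$rarefaction_depth,
                                    seed = cfg$seed + 10L))
    if (ncol(rare) < 4L)
      stop("fewer than 4 samples survive rarefaction; lower rarefaction_depth")
    um <- unifrac_matrix(comm$tree, rare, weighted = FALSE)
    f1 <- file.path(out_dir, "unifrac", "unifrac_unweighted.tsv")
    write_square_tsv(um, f1)
    hab <- stats::setNames(comm$metadata$habitat, comm$metadata$sample_id)[colnames(rare)]
    pm <- permanova(um, hab, n_perm = cfg$unifrac$n_perm, seed = cfg$seed + 11L)
    wm <- unifrac_matrix(comm$tree, rare, weighted = TRUE)
    pmw <- permanova(wm, hab, n_perm = cfg$unifrac$n_perm, seed = cfg$seed + 12L)
    f2 <- file.path(out_dir, "unifrac", "permanova.tsv")
    utils::write.table(
      data.frame(metric = c("unweighted_unifrac", "weighted_unifrac"),
                 F = c(pm$F, pmw$F), R2 = c(pm$R2, pmw$R2), p = c(pm$p, pmw$p),
                 n_perm = cfg$unifrac$n_perm),
      f2, sep = "\t", quote = FALSE, row.names = FALSE)
    pooled <- pooled_group_unifrac(comm$tree, rare, comm$metadata, comm$lineage,
                                   rank = cfg$unifrac$pooled_rank)
    f3 <- file.path(out_dir, "unifrac", "pooled_group_unifrac.tsv")
    utils::write.table(pooled, f3, sep = "\t", quote = FALSE, row.names = FALSE)
    zt <- group_unifrac_ztests(comm$tree, rare, comm$metadata, comm$lineage,
                               rank = cfg$unifrac$rank, n_rand = cfg$unifrac$n_rand,
                               seed = cfg$seed + 13L)
    f4 <- file.path(out_dir, "unifrac", "group_ztests.tsv")
    utils::write.table(zt, f4, sep = "\t", quote = FALSE, row.names = FALSE)
    record("unifrac", cfg$unifrac, c(f1, f2, f3, f4))
  }

  if ("shared" %in% cfg$stages) {
    dir.create(file.path(out_dir, "shared"), showWarnings = FALSE)
    rep <- find_shared_taxa(comm$counts, comm$metadata, comm$lineage, rank = cfg$shared$rank)
    f1 <- file.path(out_dir, "shared", "shared_taxa.tsv")
    utils::write.table(data.frame(taxon_id = rep$shared_taxa), f1,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    f2 <- file.path(out_dir, "shared", "shared_by_group.tsv")
    utils::write.table(rep$by_group, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(f1, f2)
    for (hb in c("marine", "freshwater")) {
      acc <- tryCatch(
        accumulation_curve(comm$counts, comm$metadata, axis_habitat = hb,
                           n_orderings = cfg$shared$n_orderings, seed = cfg$seed + 20L),
        error = function(e) NULL)
      if (!is.null(acc)) {
        f <- file.path(out_dir, "shared", sprintf("accumulation_%s.tsv", hb))
        utils::write.table(acc, f, sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, f)
      }
    }
    fe <- fold_enrichment(comm$counts, comm$lineage, comm$metadata, rank = cfg$shared$rank)
    f3 <- file.path(out_dir, "shared", "fold_enrichment.tsv")
    utils::write.table(fe, f3, sep = "\t", quote = FALSE, row.names = FALSE)
    record("shared", cfg$shared, c(files, f3))
  }

  if ("detect" %in% cfg$stages) {
    dir.create(file.path(out_dir, "detect"), showWarnings = FALSE)
    dc <- cfg$detect
    out <- list(
      p_zero_reads = detection_probability(dc$pop_density, dc$community_density,
                                           dc$library_size, k = 0L),
      p_one_read = detection_probability(dc$pop_density, dc$community_density,
                                         dc$library_size, k = 1L),
      expected_appearances = stats::setNames(as.list(establishment_appearances(dc$s)),
                                             paste0("s_", dc$s)),
      census_cells = census_size(dc$pop_density, dc$area_m2, dc$depth_m)
    )
    f <- file.path(out_dir, "detect", "detection.json")
    jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA)
    record("detect", dc, f)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
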