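#' Specification for a synthetic marine--freshwater community
#'
#' Bundles every knob of the synthetic data generator: a dated phylogeny,
#' habitat assignments with a controlled number of marine--freshwater
#' transition events, aligned sequences evolved along the tree, and
#' taxon-by-sample count tables with a realistic rare tail.
#'
#' Sequence divergences are expressed as fractional raw sequence distance
#' (1 - identity); internally they are converted to expected substitutions
#' per site under the equal-rates four-state model, so a transition placed
#' at divergence `d` yields a cross-habitat tip pair whose *expected*
#' proportion of differing sites is exactly `d`.
#'
#' @param n_taxa number of tips (taxa) in the simulated tree.
#' @param alignment_length alignment width in positions; the default 290
#'   matches the V4 amplicon size the scan statistic is designed for.
#' @param n_transitions number of habitat-transition events (clade flips).
#' @param transition_divergences numeric vector, one fractional sequence
#'   distance in `[0, 1]` per transition; the realized nearest cross-habitat
#'   pair of each event is engineered to sit at this divergence.
#' @param n_marine_samples,n_freshwater_samples samples per habitat.
#' @param library_size_range integer interval `c(lo, hi)` from which library
#'   sizes are drawn uniformly.
#' @param abundance_lognormal_mu_sigma `c(meanlog, sdlog)` of the log-normal
#'   relative-abundance distribution.
#' @param rare_fraction fraction of taxa forced near the detection limit
#'   (expected per-sample count below one read).
#' @param immigrant_weight multiplicative weight applied to a taxon's
#'   abundance when it is sampled outside its home habitat; small positive
#'   values put cross-habitat immigrants near the detection limit, `0`
#'   disables cross-habitat observation entirely.
#' @param tree_height tree height in expected substitutions per site; sets
#'   the background divergence between long-separated clades.
#' @param seed integer seed; all stochastic draws of the generator flow
#'   from this one value.
#'
#' @return an object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_taxa = 48L,
                           alignment_length = 290L,
                           n_transitions = 1L,
                           transition_divergences = 0.04,
                           n_marine_samples = 8L,
                           n_freshwater_samples = 8L,
                           library_size_range = c(5000L, 20000L),
                           abundance_lognormal_mu_sigma = c(0, 1.5),
                           rare_fraction = 0.25,
                           immigrant_weight = 5e-4,
                           tree_height = 0.35,
                           seed = 1L) {
  spec <- list(
    n_taxa = as.integer(n_taxa),
    alignment_length = as.integer(alignment_length),
    n_transitions = as.integer(n_transitions),
    transition_divergences = as.numeric(transition_divergences),
    n_marine_samples = as.integer(n_marine_samples),
    n_freshwater_samples = as.integer(n_freshwater_samples),
    library_size_range = as.integer(library_size_range),
    abundance_lognormal_mu_sigma = as.numeric(abundance_lognormal_mu_sigma),
    rare_fraction = as.numeric(rare_fraction),
    immigrant_weight = as.numeric(immigrant_weight),
    tree_height = as.numeric(tree_height),
    seed = as.integer(seed)
  )
  if (spec$n_taxa < 2L) stop("n_taxa must be at least 2")
  if (spec$alignment_length < 1L) stop("alignment_length must be positive")
  if (spec$n_transitions < 0L) stop("n_transitions must be non-negative")
  if (length(spec$transition_divergences) != spec$n_transitions)
    stop("transition_divergences must have one entry per transition")
  if (any(spec$transition_divergences < 0 | spec$transition_divergences > 1))
    stop("transition divergences must lie in [0, 1]")
  if (length(spec$library_size_range) != 2L ||
      any(spec$library_size_range < 1L) ||
      diff(spec$library_size_range) < 0L)
    stop("library_size_range must be an increasing integer interval with sizes >= 1")
  if (spec$rare_fraction < 0 || spec$rare_fraction > 1)
    stop("rare_fraction must lie in [0, 1]")
  if (spec$immigrant_weight < 0) stop("immigrant_weight must be non-negative")
  if (spec$tree_height <= 0) stop("tree_height must be positive")
  if (spec$n_marine_samples < 1L || spec$n_freshwater_samples < 1L)
    stop("need at least one sample per habitat")
  class(spec) <- "synthetic_spec"
  spec
}

## Jukes-Cantor-type conversions between expected substitutions per site (t)
## and expected raw proportion of differing sites (p), equal-rates 4 states.
jc_p_from_t <- function(t) 0.75 * (1 - exp(-4 * t / 3))
jc_t_from_p <- function(p) {
  if (any(p >= 0.75)) stop("raw distance >= 0.75 is unreachable under the equal-rates model")
  -0.75 * log(1 - 4 * p / 3)
}

#' Simulate a dated phylogeny for a synthetic community
#'
#' Pure-birth (Yule) tree with unit speciation rate, rescaled so the root
#' height equals `spec$tree_height` expected substitutions per site. The
#' tree is ultrametric, which lets habitat transitions be placed at exact
#' expected sequence divergences.
#'
#' @param spec a [synthetic_spec()].
#' @return a rooted binary `phylo` object with `spec$n_taxa` tips.
#' @export
simulate_tree <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_taxa < 2L) stop("n_taxa must be at least 2")
  set.seed(spec$seed)
  if (spec$n_taxa == 2L) {
    tr <- ape::read.tree(text = sprintf("(t1:%f,t2:%f);", spec$tree_height, spec$tree_height))
  } else {
    tr <- ape::rphylo(spec$n_taxa, birth = 1, death = 0)
    depth <- ape::node.depth.edgelength(tr)
    tr$edge.length <- tr$edge.length * (spec$tree_height / max(depth))
  }
  tr
}

## Node heights (distance to the most distant descendant tip is not what we
## want: for an ultrametric tree height = tree height - root distance).
node_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth) - depth
  h[seq_len(length(tree$tip.label))] <- 0
  h
}

## all nodes (tips and internals) inside the clade of `node`
clade_nodes <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  c(node, unlist(lapply(kids, clade_nodes, tree = tree)))
}

#' Assign habitats with controlled transition events
#'
#' The root receives the base habitat (marine). For each requested
#' transition a small internal clade is selected and its subtree flipped to
#' the opposite habitat; the local node heights are rescaled so the nearest
#' cross-habitat tip pair created by the event sits at exactly the requested
#' fractional sequence divergence (expected scale). Descendant clades of
#' the rescaled node are compressed well below the stem so the flipped and
#' sister lineages behave as tight, recently diverged populations.
#'
#' @param tree ultrametric `phylo` from [simulate_tree()].
#' @param spec the [synthetic_spec()] used to build `tree`.
#' @return a `synthetic_truth` list: `tree` (rescaled), `habitat` (named
#'   vector over tips), `base_habitat`, `transitions` (data frame with the
#'   selected node, tips flipped, requested and realized divergence), and
#'   `expected_shared` (taxa eligible to appear in both habitats through
#'   immigrant sampling; empty when `immigrant_weight == 0`).
#' @export
assign_habitats <- function(tree, spec) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  n_internal <- tree$Nnode
  if (spec$n_transitions > n_internal)
    stop("more transitions requested than internal nodes available")
  set.seed(spec$seed + 1L)

  base_habitat <- "marine"
  other <- "freshwater"
  habitat <- stats::setNames(rep(base_habitat, ntip), tree$tip.label)

  h <- node_heights(tree)
  root <- ntip + 1L
  parent_of <- integer(ntip + n_internal)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]

  clade_cache <- lapply(seq_len(ntip + n_internal), function(nd) clade_nodes(tree, nd))
  clade_tips <- lapply(clade_cache, function(v) v[v <= ntip])

  locked <- logical(ntip + n_internal)
  shrink <- 0.002  # subtree heights are pushed to <= shrink * stem height
  transitions <- vector("list", spec$n_transitions)

  for (i in seq_len(spec$n_transitions)) {
    d <- spec$transition_divergences[i]
    if (d > 0 && d < 1 / spec$alignment_length)
      stop(sprintf("transition divergence %.4g is below the resolution of a %d-position alignment",
                   d, spec$alignment_length))
    if (d >= 0.75)
      stop("transition divergence >= 0.75 is unattainable under the equal-rates model")
    target_h <- jc_t_from_p(d) / 2  # stem node height in subst/site

    ## the surrounding background divergence must exceed the transition
    ## divergence by several binomial standard errors of a realized
    ## sequence distance, or the event is not recoverable from sequences
    margin_p <- max(0.03, 4 * sqrt(d * (1 - d) / spec$alignment_length))
    min_gp_h <- if (d + margin_p >= 0.74) Inf else jc_t_from_p(d + margin_p) / 2

    ## candidate flip nodes: internal, not root, parent not root, region
    ## untouched, grandparent deep enough to leave the margin
    cand <- setdiff(seq(ntip + 1L, ntip + n_internal), root)
    cand <- cand[parent_of[cand] != root]
    cand <- Filter(function(v) {
      p <- parent_of[v]
      gp <- parent_of[p]
      if (locked[v] || locked[p]) return(FALSE)
      region <- clade_cache[[p]]
      if (any(locked[region])) return(FALSE)
      if (any(habitat[tree$tip.label[clade_tips[[p]]]] != base_habitat)) return(FALSE)
      h[gp] > max(target_h * 1.05, min_gp_h) + 1e-9
    }, cand)
    if (length(cand) == 0L)
      stop(sprintf("no feasible placement for a transition at divergence %.4g (tree too shallow or crowded)", d))

    ## prefer the smallest affected region (fewest tips under the stem node)
    sizes <- vapply(cand, function(v) length(clade_tips[[parent_of[v]]]), integer(1))
    cand <- cand[sizes == min(sizes)]
    v <- if (length(cand) == 1L) cand else sample(cand, 1L)
    p <- parent_of[v]

    ## rescale: stem node at target height, both child subtrees compressed
    h[p] <- target_h
    for (child in tree$edge[tree$edge[, 1] == p, 2]) {
      sub <- clade_cache[[child]]
      sub_int <- sub[sub > ntip]
      if (length(sub_int) > 0L) {
        mx <- max(h[sub_int])
        h[sub_int] <- if (target_h == 0 || mx == 0) 0 else h[sub_int] * (shrink * target_h / mx)
      }
    }
    locked[clade_cache[[p]]] <- TRUE
    locked[p] <- TRUE

    flipped <- tree$tip.label[clade_tips[[v]]]
    habitat[flipped] <- other
    transitions[[i]] <- data.frame(node = v, parent = p, stem_height = target_h,
                                   n_tips_flipped = length(flipped),
                                   requested_divergence = d, realized_divergence = NA_real_,
                                   stringsAsFactors = FALSE)
  }

  ## rebuild edge lengths from the adjusted heights
  tree$edge.length <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
  if (any(tree$edge.length < -1e-12))
    stop("internal error: habitat rescaling produced a negative branch length")
  tree$edge.length[tree$edge.length < 0] <- 0

  ## realized (expected-scale) nearest cross-habitat divergence per event
  if (spec$n_transitions > 0L) {
    pat <- ape::cophenetic.phylo(tree)
    pmat <- jc_p_from_t(pat)
    for (i in seq_len(spec$n_transitions)) {
      v <- transitions[[i]]$node
      inside <- tree$tip.label[clade_tips[[v]]]
      outside <- setdiff(names(habitat)[habitat != habitat[inside[1]]], inside)
      transitions[[i]]$realized_divergence <-
        if (length(outside) > 0L) min(pmat[inside, outside, drop = FALSE]) else NA_real_
    }
  }

  truth <- list(
    tree = tree,
    habitat = habitat,
    base_habitat = base_habitat,
    transitions = if (spec$n_transitions > 0L) do.call(rbind, transitions) else
      data.frame(node = integer(0), parent = integer(0), stem_height = numeric(0),
                 n_tips_flipped = integer(0),
                 requested_divergence = numeric(0), realized_divergence = numeric(0)),
    flipped = lapply(transitions, function(tr) tree$tip.label[clade_tips[[tr$node]]]),
    expected_shared = if (spec$immigrant_weight > 0) names(habitat) else character(0)
  )
  class(truth) <- "synthetic_truth"
  truth
}

#' Evolve aligned sequences along a tree
#'
#' Site-independent evolution under the equal-rates four-state model
#' (uniform base frequencies, equal exchangeabilities), with branch lengths
#' interpreted as expected substitutions per site.
#'
#' When the habitat `truth` is supplied, each transition's divergence is
#' engineered rather than sampled: the stem branches flanking the
#' transition node evolve no substitutions (their length is shifted onto
#' the stem's parent edge, leaving distances to the rest of the tree
#' unchanged) and exactly `round(d * alignment_length)` randomly chosen
#' sites of the flipped clade are substituted. The nearest cross-habitat
#' sequence pair then differs at the requested fraction of sites to within
#' rounding and the residual evolution of the compressed subtrees, instead
#' of fluctuating with the binomial site-sampling noise of free evolution
#' (which has a standard deviation of several sites at this alignment
#' length).
#'
#' @param tree a `phylo` with branch lengths (typically `truth$tree`).
#' @param spec the [synthetic_spec()].
#' @param truth optional `synthetic_truth`; when given, transition
#'   divergences are realized exactly as described above.
#' @return character matrix (tips x positions) over `A`,`C`,`G`,`T`, rows
#'   named by tip label in `tree$tip.label` order.
#' @export
evolve_sequences <- function(tree, spec, truth = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 tips")
  if (spec$alignment_length < 1L) stop("alignment_length must be >= 1")
  set.seed(spec$seed + 2L)

  sim_tree <- tree
  if (!is.null(truth) && nrow(truth$transitions) > 0L) {
    for (i in seq_len(nrow(truth$transitions))) {
      p <- truth$transitions$parent[i]
      stem_edges <- which(sim_tree$edge[, 1] == p)
      shift <- max(sim_tree$edge.length[stem_edges])
      sim_tree$edge.length[stem_edges] <- 0
      up <- which(sim_tree$edge[, 2] == p)
      if (length(up) == 1L) sim_tree$edge.length[up] <- sim_tree$edge.length[up] + shift
    }
  }

  sim <- phangorn::simSeq(sim_tree, l = spec$alignment_length, type = "DNA")
  m <- toupper(as.character(sim))
  m <- m[tree$tip.label, , drop = FALSE]

  if (!is.null(truth) && nrow(truth$transitions) > 0L) {
    bases <- c("A", "C", "G", "T")
    L <- spec$alignment_length
    for (i in seq_len(nrow(truth$transitions))) {
      k <- round(truth$transitions$requested_divergence[i] * L)
      if (k == 0L) next
      sites <- sample.int(L, k)
      offset <- sample.int(3L, k, replace = TRUE)
      for (tip in truth$flipped[[i]]) {
        idx <- match(m[tip, sites], bases)
        m[tip, sites] <- bases[((idx - 1L + offset) %% 4L) + 1L]
      }
    }
  }
  m
}

#' Draw taxon-by-sample count tables
#'
#' Relative abundances are log-normal with a configurable rare tail: a
#' `rare_fraction` of taxa is rescaled so its expected per-sample count is
#' below one read. Each sample draws a library size uniformly from
#' `library_size_range` and counts multinomially; taxa native to the
#' sample's habitat carry full weight while cross-habitat taxa are
#' down-weighted by `immigrant_weight`, putting shared taxa near the
#' detection limit.
#'
#' @param truth a `synthetic_truth` from [assign_habitats()].
#' @param spec the [synthetic_spec()].
#' @return list with `counts` (integer matrix, taxa x samples) and
#'   `metadata` (data frame: sample_id, habitat, site, depth_class).
#' @export
sample_counts <- function(truth, spec) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(truth, "synthetic_truth"))
  set.seed(spec$seed + 3L)
  taxa <- names(truth$habitat)
  n <- length(taxa)

  w <- stats::rlnorm(n, spec$abundance_lognormal_mu_sigma[1], spec$abundance_lognormal_mu_sigma[2])
  n_rare <- round(spec$rare_fraction * n)
  if (n_rare > 0L && n_rare < n) {
    rare <- sample.int(n, n_rare)
    l_ref <- mean(spec$library_size_range)
    rel_target <- stats::runif(n_rare, 0.05, 0.9) / l_ref
    total <- sum(w[-rare]) / (1 - sum(rel_target))
    w[rare] <- rel_target * total
  }

  meta <- data.frame(
    sample_id = c(sprintf("M%02d", seq_len(spec$n_marine_samples)),
                  sprintf("F%02d", seq_len(spec$n_freshwater_samples))),
    habitat = c(rep("marine", spec$n_marine_samples),
                rep("freshwater", spec$n_freshwater_samples)),
    stringsAsFactors = FALSE
  )
  meta$site <- paste0("site_", meta$sample_id)
  meta$depth_class <- sample(c("surface", "deep"), nrow(meta), replace = TRUE)

  lo <- spec$library_size_range[1]; hi <- spec$library_size_range[2]
  sizes <- if (lo == hi) rep(lo, nrow(meta)) else sample(seq(lo, hi), nrow(meta), replace = TRUE)

  counts <- matrix(0L, n, nrow(meta), dimnames = list(taxa, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    home <- truth$habitat == meta$habitat[j]
    wt <- w * ifelse(home, 1, spec$immigrant_weight)
    if (sum(wt) <= 0)
      stop(sprintf("sample %s has no taxa with positive sampling weight", meta$sample_id[j]))
    counts[, j] <- as.integer(stats::rmultinom(1, sizes[j], wt / sum(wt)))
  }
  list(counts = counts, metadata = meta)
}

#' Derive nested lineage strings from the tree
#'
#' Clades are cut at fixed fractions of the tree height to define phylum,
#' class, order, family and genus labels, giving each taxon a
#' semicolon-delimited five-rank lineage consistent with its phylogenetic
#' position.
#'
#' @param tree a `phylo` (typically `truth$tree`).
#' @param cut_fractions named fractions of tree height at which each rank
#'   is cut (rootward = coarser).
#' @return data frame with `taxon_id` and `lineage` plus one column per rank.
#' @export
make_lineage <- function(tree,
                         cut_fractions = c(phylum = 0.85, class = 0.60,
                                           order = 0.40, family = 0.25, genus = 0.12)) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  h <- node_heights(tree)
  H <- max(h)
  root <- ntip + 1L
  prefix <- c(phylum = "Phy", class = "Cls", order = "Ord", family = "Fam", genus = "Gen")

  cols <- list()
  for (rk in names(cut_fractions)) {
    thr <- cut_fractions[[rk]] * H
    grp <- integer(ntip)
    for (tip in seq_len(ntip)) {
      path <- ape::nodepath(tree, root, tip)
      grp[tip] <- path[which(h[path] <= thr + 1e-12)[1]]
    }
    cols[[rk]] <- sprintf("%s%02d", prefix[[rk]], match(grp, sort(unique(grp))))
  }
  out <- data.frame(taxon_id = tree$tip.label, stringsAsFactors = FALSE)
  for (rk in names(cols)) out[[rk]] <- cols[[rk]]
  out$lineage <- apply(out[, names(cut_fractions), drop = FALSE], 1, paste, collapse = ";")
  out
}

#' Simulate a full synthetic community
#'
#' Convenience wrapper running [simulate_tree()], [assign_habitats()],
#' [evolve_sequences()], [sample_counts()] and [make_lineage()] in order.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_community` with elements `spec`,
#'   `tree`, `truth`, `seqs`, `counts`, `metadata`, `lineage`.
#' @export
simulate_community <- function(spec) {
  tree0 <- simulate_tree(spec)
  truth <- assign_habitats(tree0, spec)
  seqs <- evolve_sequences(truth$tree, spec, truth)
  cs <- sample_counts(truth, spec)
  lin <- make_lineage(truth$tree)
  out <- list(spec = spec, tree = truth$tree, truth = truth, seqs = seqs,
              counts = cs$counts, metadata = cs$metadata, lineage = lin)
  class(out) <- "synthetic_community"
  out
}

#' Write a synthetic community to plain-text files
#'
#' Writes an aligned FASTA, a newick tree, counts/metadata/lineage TSVs and
#' a truth JSON under `dir`. All writers are deterministic, so identical
#' communities produce byte-identical files.
#'
#' @param comm a `synthetic_community`.
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of the file paths written.
#' @export
write_community <- function(comm, dir) {
  stopifnot(inherits(comm, "synthetic_community"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "sequences.fasta"),
    tree = file.path(dir, "tree.nwk"),
    counts = file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    lineage = file.path(dir, "lineage.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_fasta(comm$seqs, paths["fasta"])
  ape::write.tree(comm$tree, file = paths["tree"])
  write_counts_tsv(comm$counts, paths["counts"])
  utils::write.table(comm$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(comm$lineage[, c("taxon_id", "lineage")], paths["lineage"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_json <- list(
    base_habitat = comm$truth$base_habitat,
    habitat = as.list(comm$truth$habitat),
    transitions = comm$truth$transitions,
    expected_shared = comm$truth$expected_shared
  )
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
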