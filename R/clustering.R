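#' Farthest-neighbor clustering at every cutoff on a fine grid
#'
#' Complete-linkage agglomerative clustering of a pairwise distance matrix,
#' with the full merge trajectory materialized as one partition per cutoff
#' on a regular grid from 0 up to the smallest cutoff at which all
#' sequences collapse into a single cluster. A merge at cutoff `t` requires
#' *all* cross-pair distances to be at most `t`, so clusters formed at a
#' given identity threshold are guaranteed internally consistent at that
#' identity. Ties in merge order are broken by the lexicographically lowest
#' pair of smallest-member indices, making the trajectory deterministic.
#'
#' @param dm symmetric distance matrix with zero diagonal (from
#'   [pairwise_distance()]).
#' @param grid_step cutoff grid step; the default 0.001 scans identity
#'   thresholds at a precision of 1,000.
#' @return object of class `multithreshold_clustering`: `cutoffs` (grid),
#'   `membership` (sequences x cutoffs integer matrix; entries are the
#'   smallest member index of each cluster), `merges` (height and merged
#'   representatives in order), `ids`, `collapse` (height of the final
#'   merge).
#' @export
farthest_neighbor_cluster <- function(dm, grid_step = 0.001) {
  if (!is.matrix(dm) || nrow(dm) == 0L) stop("empty or invalid distance matrix")
  if (nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  if (grid_step <= 0 || grid_step > 0.01) stop("grid_step must lie in (0, 0.01]")
  n <- nrow(dm)
  ids <- rownames(dm)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  eps <- 1e-12

  heights <- numeric(max(n - 1L, 0L))
  rep_a <- integer(max(n - 1L, 0L))
  rep_b <- integer(max(n - 1L, 0L))
  if (n > 1L) {
    D <- dm
    diag(D) <- Inf
    active <- rep(TRUE, n)
    smallest <- seq_len(n)  # smallest original member index per active cluster
    for (k in seq_len(n - 1L)) {
      Dv <- D
      Dv[!active, ] <- Inf
      Dv[, !active] <- Inf
      mn <- min(Dv)
      cand <- which(Dv <= mn + eps, arr.ind = TRUE)
      cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
      key1 <- pmin(smallest[cand[, 1]], smallest[cand[, 2]])
      key2 <- pmax(smallest[cand[, 1]], smallest[cand[, 2]])
      pick <- order(key1, key2)[1]
      i <- cand[pick, 1]; j <- cand[pick, 2]
      if (smallest[j] < smallest[i]) { tmp <- i; i <- j; j <- tmp }
      heights[k] <- max(D[i, j], 0)
      rep_a[k] <- smallest[i]; rep_b[k] <- smallest[j]
      ## complete linkage: distance to the union is the max
      newd <- pmax(D[i, ], D[j, ])
      D[i, ] <- newd; D[, i] <- newd
      D[i, i] <- Inf
      active[j] <- FALSE
    }
  }
  collapse <- if (n > 1L) heights[n - 1L] else 0

  n_steps <- ceiling(max(collapse - eps, 0) / grid_step)
  cutoffs <- seq(0, by = grid_step, length.out = n_steps + 1L)

  membership <- matrix(0L, n, length(cutoffs), dimnames = list(ids, NULL))
  cur <- seq_len(n)
  k_merge <- 1L
  for (ci in seq_along(cutoffs)) {
    while (k_merge <= n - 1L && heights[k_merge] <= cutoffs[ci] + eps) {
      cur[cur == rep_b[k_merge]] <- rep_a[k_merge]
      k_merge <- k_merge + 1L
    }
    membership[, ci] <- cur
  }

  structure(list(cutoffs = cutoffs, membership = membership,
                 merges = data.frame(height = heights, rep_a = rep_a, rep_b = rep_b),
                 ids = ids, collapse = collapse),
            class = "multithreshold_clustering")
}

#' Partition at a given distance cutoff
#'
#' Applies every merge whose height is at most `cutoff` (to numerical
#' tolerance), so the result is exact for any cutoff, on or off the grid.
#'
#' @param clust a `multithreshold_clustering`.
#' @param cutoff a distance cutoff value.
#' @return integer vector of cluster labels (smallest member index of each
#'   cluster) named by sequence id.
#' @export
partition_at <- function(clust, cutoff) {
  stopifnot(inherits(clust, "multithreshold_clustering"))
  cur <- seq_along(clust$ids)
  m <- clust$merges
  for (k in seq_len(nrow(m))) {
    if (m$height[k] > cutoff + 1e-12) break
    cur[cur == m$rep_b[k]] <- m$rep_a[k]
  }
  stats::setNames(cur, clust$ids)
}

#' Greedy abundance-sorted preclustering
#'
#' Denoising step: sequences are visited in decreasing abundance and each
#' one is absorbed by the most abundant already-retained sequence within
#' `max_diffs` raw column differences; its count is added onto that
#' representative. With `max_diffs = 0` only identical sequences merge.
#'
#' @param seqs character matrix (sequences x positions), rows named.
#' @param abundance numeric vector of per-sequence total counts, in row
#'   order of `seqs`.
#' @param max_diffs maximum raw differences for absorption (>= 0).
#' @return list: `seqs` (representative rows of the input matrix),
#'   `abundance` (summed counts), `map` (named vector: input id ->
#'   representative id).
#' @export
precluster <- function(seqs, abundance, max_diffs = 2L) {
  stopifnot(is.matrix(seqs), length(abundance) == nrow(seqs))
  if (max_diffs < 0) stop("max_diffs must be >= 0")
  n <- nrow(seqs)
  ids <- rownames(seqs)
  ord <- order(-abundance, seq_len(n))
  reps <- integer(0)
  rep_abund <- numeric(0)
  map <- stats::setNames(character(n), ids)
  for (i in ord) {
    absorbed <- FALSE
    for (r in seq_along(reps)) {
      if (sum(seqs[i, ] != seqs[reps[r], ]) <= max_diffs) {
        rep_abund[r] <- rep_abund[r] + abundance[i]
        map[ids[i]] <- ids[reps[r]]
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) {
      reps <- c(reps, i)
      rep_abund <- c(rep_abund, abundance[i])
      map[ids[i]] <- ids[i]
    }
  }
  list(seqs = seqs[reps, , drop = FALSE],
       abundance = stats::setNames(rep_abund, ids[reps]),
       map = map)
}
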