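## does any 2x2 checkerboard submatrix exist? exact check over row pairs
has_checkerboard <- function(m) {
  nr <- nrow(m)
  if (nr < 2L || ncol(m) < 2L) return(FALSE)
  for (i in seq_len(nr - 1L)) {
    xi <- m[i, ]
    for (j in seq(i + 1L, nr)) {
      xj <- m[j, ]
      if (any(xi == 1 & xj == 0) && any(xi == 0 & xj == 1)) return(TRUE)
    }
  }
  FALSE
}

#' Independent-swap randomizations of a presence-absence matrix
#'
#' Markov chain of 2x2 checkerboard submatrix swaps: a random pair of rows
#' and columns is drawn and, when the induced submatrix is a checkerboard
#' (`10/01` or `01/10`), its entries are flipped. Every draw preserves all
#' row and column sums exactly, so the null keeps each taxon's occupancy
#' and each sample's richness while shuffling co-occurrence. The chain
#' burns in for `10 * length(m)` attempted swaps and thins by `length(m)`
#' attempts between draws.
#'
#' @param m binary (0/1) matrix, typically taxa x samples presence.
#' @param n_rand number of randomized matrices to return (default 1000).
#' @param seed integer seed.
#' @return list of `n_rand` matrices with the margins of `m`. If `m` has
#'   no swappable checkerboard the originals are returned with a warning.
#' @export
independent_swap_null <- function(m, n_rand = 1000L, seed = 1L) {
  if (!is.matrix(m) || !all(m %in% c(0, 1)))
    stop("m must be a binary 0/1 matrix")
  if (!has_checkerboard(m)) {
    warning("matrix has no swappable 2x2 checkerboard; returning originals")
    return(replicate(n_rand, m, simplify = FALSE))
  }
  set.seed(seed)
  nr <- nrow(m); nc <- ncol(m)
  cells <- nr * nc
  rs <- rowSums(m); cs <- colSums(m)
  cur <- m
  sweep_attempts <- function(k) {
    for (it in seq_len(k)) {
      r <- sample.int(nr, 2L)
      c <- sample.int(nc, 2L)
      a <- cur[r[1], c[1]]; b <- cur[r[1], c[2]]
      cc <- cur[r[2], c[1]]; dd <- cur[r[2], c[2]]
      if (a == dd && b == cc && a != b) {
        cur[r[1], c[1]] <<- b; cur[r[1], c[2]] <<- a
        cur[r[2], c[1]] <<- dd; cur[r[2], c[2]] <<- cc
      }
    }
  }
  sweep_attempts(10L * cells)
  draws <- vector("list", n_rand)
  for (d in seq_len(n_rand)) {
    sweep_attempts(cells)
    stopifnot(all(rowSums(cur) == rs), all(colSums(cur) == cs))
    draws[[d]] <- cur
  }
  draws
}

#' One-sample z test against a null ensemble
#'
#' Tests whether an observed statistic exceeds its randomization null:
#' `z = (observed - mean(null)) / sd(null)`, with a one-sided upper-tail
#' normal p-value and a Bonferroni correction across the number of groups
#' tested.
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of randomized statistics (length >= 2).
#' @param n_groups number of groups tested, for the Bonferroni factor.
#' @return list: `z`, `p`, `p_bonferroni`, `mean_null`, `sd_null`.
#' @export
z_test <- function(observed, null_values, n_groups = 1L) {
  if (length(null_values) < 2L) stop("need at least 2 null values")
  mu <- mean(null_values)
  sigma <- stats::sd(null_values)
  if (sigma == 0) stop("null ensemble has zero standard deviation")
  z <- (observed - mu) / sigma
  p <- stats::pnorm(z, lower.tail = FALSE)
  list(z = z, p = p, p_bonferroni = min(1, p * n_groups),
       mean_null = mu, sd_null = sigma)
}

#' Permutation PerMANOVA for a single grouping factor
#'
#' Pseudo-F from the distance matrix:
#' `F = (SS_between / (k - 1)) / (SS_within / (N - k))` with
#' `SS_total = sum_{i<j} d_ij^2 / N` and within-group sums computed from
#' within-group distances; `R^2 = SS_between / SS_total`. Significance by
#' random label permutation, `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param d square symmetric distance matrix (or `dist`).
#' @param labels grouping vector, one per sample; at least two levels and
#'   at least two samples per level.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list: `F`, `R2`, `p`, `n_perm`, `df` (between, within).
#' @export
permanova <- function(d, labels, n_perm = 999L, seed = 1L) {
  D2 <- as.matrix(d)^2
  N <- nrow(D2)
  labels <- as.factor(labels)
  if (length(labels) != N) stop("labels must match the distance matrix dimension")
  k <- nlevels(droplevels(labels))
  if (k < 2L) stop("all samples carry one label; nothing to test")
  if (any(table(labels) < 2L)) stop("each group needs at least 2 samples")

  ss_within <- function(lab) {
    s <- 0
    for (lv in levels(lab)) {
      idx <- which(lab == lv)
      s <- s + sum(D2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ss_t <- sum(D2) / (2 * N)
  ss_w <- ss_within(labels)
  ss_b <- ss_t - ss_w
  f_obs <- (ss_b / (k - 1)) / (ss_w / (N - k))
  r2 <- ss_b / ss_t

  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    lab_p <- labels[sample.int(N)]
    ss_wp <- ss_within(lab_p)
    f_p <- ((ss_t - ss_wp) / (k - 1)) / (ss_wp / (N - k))
    if (f_p >= f_obs - 1e-12) exceed <- exceed + 1L
  }
  list(F = f_obs, R2 = r2, p = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm, df = c(between = k - 1L, within = N - k))
}
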