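#' Pairwise sequence distances with the one-gap convention
#'
#' Fractional distance between every pair of aligned sequences:
#' differences divided by compared columns. Comparison for a pair starts at
#' the first and ends at the last alignment column where both sequences
#' have a base (terminal gaps are ignored). Within that window, columns
#' where both sequences are gapped and columns where either has an `N` are
#' excluded; a maximal run of gap columns in one sequence counts as a
#' single difference, while every mismatched base pair counts one. This is
#' the convention fine-scale amplicon workflows use when distances feed an
#' identity-threshold clustering.
#'
#' @param seqs character matrix (sequences x positions) over
#'   `A`,`C`,`G`,`T`,`-`,`N`, rows named by sequence id.
#' @return symmetric numeric matrix of distances in `[0, 1]` with zero
#'   diagonal, dimnames = sequence ids.
#' @export
pairwise_distance <- function(seqs) {
  if (!is.matrix(seqs)) stop("seqs must be a character matrix")
  if (nrow(seqs) < 2L) stop("need at least 2 sequences")
  bad <- setdiff(unique(as.vector(seqs)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad) > 0L)
    stop(sprintf("alphabet outside {A,C,G,T,-,N}: %s", paste(bad, collapse = ",")))
  n <- nrow(seqs)
  ids <- rownames(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))

  has_gap_or_n <- any(seqs == "-") || any(seqs == "N")
  if (!has_gap_or_n) {
    ## fast path: plain Hamming fraction
    L <- ncol(seqs)
    for (i in seq_len(n - 1L)) {
      xi <- seqs[i, ]
      for (j in seq(i + 1L, n)) {
        d[i, j] <- d[j, i] <- sum(xi != seqs[j, ]) / L
      }
    }
    return(d)
  }

  is_base <- seqs != "-" & seqs != "N"
  first_base <- apply(seqs != "-", 1, function(z) which(z)[1])
  last_base <- apply(seqs != "-", 1, function(z) max(which(z)))
  for (i in seq_len(n - 1L)) {
    a <- seqs[i, ]
    for (j in seq(i + 1L, n)) {
      b <- seqs[j, ]
      lo <- max(first_base[i], first_base[j])
      hi <- min(last_base[i], last_base[j])
      if (is.na(lo) || is.na(hi) || lo > hi) { d[i, j] <- d[j, i] <- NA_real_; next }
      idx <- lo:hi
      aa <- a[idx]; bb <- b[idx]
      keep <- !(aa == "-" & bb == "-") & aa != "N" & bb != "N"
      aa <- aa[keep]; bb <- bb[keep]
      if (length(aa) == 0L) { d[i, j] <- d[j, i] <- NA_real_; next }
      gap_a <- aa == "-"
      gap_b <- bb == "-"
      mism <- sum(aa != bb & !gap_a & !gap_b)
      runs <- function(g) if (!any(g)) 0L else sum(rle(g)$values)
      diffs <- mism + runs(gap_a) + runs(gap_b)
      d[i, j] <- d[j, i] <- diffs / length(aa)
    }
  }
  d
}
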