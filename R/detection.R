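#' Probability of observing a rare population k times in a library
#'
#' Assuming sequencing samples cells in proportion to their abundance, the
#' number of reads drawn from a population at density `pop_density` within
#' a community at `community_density` is binomial with
#' `p = pop_density / community_density` over `library_size` draws. For
#' example, a population at 1 cell/ml in a community of 500,000 cells/ml
#' goes entirely undetected 74% of the time in a 150,000-read library,
#' and yields exactly one read 22% of the time.
#'
#' @param pop_density population density, cells per ml (>= 0).
#' @param community_density total community density, cells per ml (> 0).
#' @param library_size number of sequences in the library (>= 1).
#' @param k number of reads observed (0 <= k <= library_size).
#' @param method `"binomial"` (canonical) or `"poisson"` (approximation,
#'   accurate to four decimals when `p < 1e-4`).
#' @return probability of exactly `k` reads.
#' @export
detection_probability <- function(pop_density, community_density, library_size,
                                  k = 0L, method = c("binomial", "poisson")) {
  method <- match.arg(method)
  if (community_density <= 0) stop("community_density must be positive")
  if (pop_density < 0) stop("pop_density must be non-negative")
  p <- pop_density / community_density
  if (p > 1) stop("pop_density exceeds community_density (p > 1)")
  if (library_size < 1) stop("library_size must be >= 1")
  if (any(k < 0 | k > library_size)) stop("k must lie in [0, library_size]")
  if (method == "binomial") {
    stats::dbinom(k, size = library_size, prob = p)
  } else {
    stats::dpois(k, lambda = library_size * p)
  }
}

#' Expected appearances of a variant before establishment
#'
#' Under the branching-process approximation, a beneficial variant with
#' selective advantage `s` escapes stochastic loss (drift) with
#' probability `2s` per independent appearance, so it must appear
#' `1 / (2s)` times on average before it becomes established. A 10%
#' advantage means five appearances on average; a 0.1% advantage means
#' 500.
#'
#' @param s selective advantage, in (0, 1].
#' @return expected number of independent appearances before establishment.
#' @export
establishment_appearances <- function(s) {
  if (any(s <= 0)) stop("selective advantage must be positive")
  if (any(s > 1)) stop("selective advantage cannot exceed 1")
  1 / (2 * s)
}

#' Census population size of a dilute aquatic population
#'
#' Converts a cell density to a whole-layer census:
#' `cells = density (cells/ml) * 1e6 (ml/m^3) * area (m^2) * depth (m)`.
#' Even one cell per ml amounts to billions of cells in a one-meter layer
#' of a small lake and quadrillions in a large one.
#'
#' @param density cells per ml (> 0).
#' @param area_m2 surface area in square meters (> 0).
#' @param depth_m layer depth in meters (> 0).
#' @return total cells in the layer.
#' @export
census_size <- function(density, area_m2, depth_m) {
  if (density <= 0 || area_m2 <= 0 || depth_m <= 0)
    stop("density, area and depth must all be positive")
  density * 1e6 * area_m2 * depth_m
}
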