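# Statistical and layout kernels behind the hist/dens/beeswarm/heatmap layer
# types. All conventions here are frozen so that rendering is deterministic:
# equal-width left-closed bins (last bin right-closed), Gaussian KDE with
# Silverman's rule, greedy beeswarm placement, complete-linkage leaf order.

#' Equal-width histogram binning
#'
#' Intervals are closed on the left and open on the right, except the last
#' bin which is closed on both sides, so every in-range value lands in
#' exactly one bin.
#'
#' @param values numeric vector (non-finite values are dropped).
#' @param bin_count number of bins, >= 1.
#' @param limits numeric pair covering the data; defaults to the data range.
#' @return `list(edges =, counts =)` with `bin_count + 1` edges; counts sum to
#'   the number of in-range values.
#' @examples
#' histogram_bins(c(0, 0.5, 1), 2, c(0, 1))$counts  # 1 2
#' @export
histogram_bins <- function(values, bin_count = 10L, limits = NULL) {
  stopifnot(bin_count >= 1L)
  values <- values[is.finite(values)]
  if (is.null(limits)) {
    limits <- if (length(values)) range(values) else c(0, 1)
  }
  if (limits[1] == limits[2]) limits <- limits + c(-0.5, 0.5)
  edges <- seq(limits[1], limits[2], length.out = bin_count + 1L)
  inr <- values >= limits[1] & values <= limits[2]
  v <- values[inr]
  idx <- pmin(floor((v - limits[1]) / (limits[2] - limits[1]) * bin_count) + 1L,
              bin_count)
  counts <- tabulate(idx, nbins = bin_count)
  list(edges = edges, counts = counts)
}

#' Gaussian kernel density estimate on a grid
#'
#' Evaluates f(g) = (1/(n h)) * sum_i phi((g - x_i)/h) with phi the standard
#' normal density. The default bandwidth is Silverman's rule of thumb,
#' 0.9 * min(sd, IQR/1.34) * n^(-1/5); for zero-variance data it falls back
#' to 1e-3 * (|mean| + 1).
#'
#' @param values numeric data, n >= 1.
#' @param bandwidth kernel bandwidth h > 0, or `NULL` for Silverman's rule.
#' @param grid evaluation points; defaults to 200 points spanning the data
#'   range extended by 3 bandwidths.
#' @return `list(grid =, density =, bandwidth =)`.
#' @export
gaussian_kde <- function(values, bandwidth = NULL, grid = NULL) {
  values <- values[is.finite(values)]
  n <- length(values)
  stopifnot(n >= 1L)
  if (is.null(bandwidth)) {
    cands <- c(stats::sd(values), stats::IQR(values) / 1.34)
    cands <- cands[!is.na(cands) & cands > 0]
    bandwidth <- if (length(cands)) 0.9 * min(cands) * n^(-1 / 5) else
      1e-3 * (abs(mean(values)) + 1)
  }
  stopifnot(bandwidth > 0)
  if (is.null(grid)) {
    grid <- seq(min(values) - 3 * bandwidth, max(values) + 3 * bandwidth,
                length.out = 200L)
  }
  z <- outer(grid, values, function(g, x) stats::dnorm((g - x) / bandwidth))
  list(grid = grid, density = rowSums(z) / (n * bandwidth),
       bandwidth = bandwidth)
}

#' Beeswarm offsets perpendicular to the value axis
#'
#' Greedy placement in order of position along the value axis (ties keep
#' input order): each point receives the smallest-magnitude offset such that
#' its center is at least `2 * radius` away from every previously placed
#' center; ties between +d and -d break toward +d.
#'
#' @param positions device-unit coordinates along the value axis.
#' @param radius marker radius in device units; `radius <= 0` returns all
#'   zeros.
#' @return Numeric offsets in input order.
#' @export
beeswarm_offsets <- function(positions, radius) {
  n <- length(positions)
  off <- numeric(n)
  if (radius <= 0 || n == 0L) return(off)
  ord <- order(positions)          # stable: ties keep input order
  placed_x <- numeric(0)
  placed_y <- numeric(0)
  min_d2 <- (2 * radius)^2
  for (i in ord) {
    x <- positions[i]
    near <- which(abs(placed_x - x) < 2 * radius)
    if (!length(near)) {
      y <- 0
    } else {
      half <- sqrt(min_d2 - (placed_x[near] - x)^2)
      cand <- c(0, placed_y[near] + half, placed_y[near] - half)
      ok <- vapply(cand, function(y0) {
        all((placed_x[near] - x)^2 + (placed_y[near] - y0)^2 >= min_d2 - 1e-9)
      }, logical(1))
      cand <- cand[ok]
      # smallest magnitude; tie toward positive
      cand <- cand[order(abs(cand), -sign(cand))]
      y <- cand[1]
    }
    off[i] <- y
    placed_x <- c(placed_x, x)
    placed_y <- c(placed_y, y)
  }
  off
}

#' Heatmap row/column order from hierarchical clustering
#'
#' Leaf order of agglomerative hierarchical clustering with Euclidean
#' distance and complete linkage, computed over the rows or the columns of a
#' numeric matrix. Missing values enter the distances pairwise-complete (the
#' usual rescaled Euclidean distance); a pair of vectors with no common
#' non-missing entry is an error.
#'
#' @param m numeric matrix.
#' @param axis `"rows"` or `"cols"`.
#' @return An integer permutation of `1..m` (1-based leaf order).
#' @export
cluster_order <- function(m, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(m))
  if (axis == "cols") m <- t(m)
  k <- nrow(m)
  if (k == 1L) return(1L)
  d <- stats::dist(m)
  if (any(is.na(d))) {
    stop("cannot order: some row pairs share no non-missing values",
         call. = FALSE)
  }
  stats::hclust(d, method = "complete")$order
}
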