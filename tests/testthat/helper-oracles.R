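# Independent reference implementations used to pin expected values.
# Deliberately naive (loops, enumeration) and kept separate from the code
# paths they check.

# Tick oracle: enumerate every step {1,2,5} x 10^k over a wide exponent
# range, keep the largest step not exceeding span/target, and emit the
# consecutive multiples covering the domain.
oracle_ticks <- function(domain, target_count) {
  lo <- min(domain); hi <- max(domain)
  if (lo == hi) return(lo)
  raw <- (hi - lo) / target_count
  steps <- sort(as.vector(outer(c(1, 2, 5), 10^(-12:12))))
  s <- max(steps[steps <= raw * (1 + 1e-9)])
  ticks <- seq(floor(lo / s + 1e-9) * s, ceiling(hi / s - 1e-9) * s, by = s)
  round(ticks / s) * s
}

# KDE oracle: double loop over grid x data.
oracle_kde <- function(values, h, grid) {
  out <- numeric(length(grid))
  for (i in seq_along(grid)) {
    acc <- 0
    for (x in values) acc <- acc + dnorm((grid[i] - x) / h)
    out[i] <- acc / (length(values) * h)
  }
  out
}

# Histogram oracle: per-value loop applying the left-closed / last-bin-
# right-closed convention directly.
oracle_hist_counts <- function(values, edges) {
  nb <- length(edges) - 1L
  counts <- integer(nb)
  for (v in values) {
    if (v < edges[1] || v > edges[nb + 1L]) next
    placed <- FALSE
    for (b in seq_len(nb - 1L)) {
      if (v >= edges[b] && v < edges[b + 1L]) {
        counts[b] <- counts[b] + 1L; placed <- TRUE; break
      }
    }
    if (!placed) counts[nb] <- counts[nb] + 1L
  }
  counts
}

# Benjamini-Hochberg oracle: explicit step-up with cumulative minimum.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * n / seq(n, 1)))
  adj[order(o)]
}

# Spearman oracle: mid-ranks then the explicit Pearson sum formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# sRGB interpolation oracle for a 2-color palette.
oracle_midpoint_color <- function(c1, c2) {
  v1 <- as.integer(grDevices::col2rgb(c1))
  v2 <- as.integer(grDevices::col2rgb(c2))
  m <- round((v1 + v2) / 2)
  grDevices::rgb(m[1], m[2], m[3], maxColorValue = 255)
}

# Pairwise non-overlap check for beeswarm layouts.
swarm_separated <- function(positions, offsets, radius) {
  n <- length(positions)
  if (n < 2L) return(TRUE)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sqrt((positions[i] - positions[j])^2 + (offsets[i] - offsets[j])^2)
      if (d < 2 * radius - 1e-9) return(FALSE)
    }
  }
  TRUE
}
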