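# Synthetic drug screen: microtiter plates of viability read-outs across
# drugs x concentrations x cell lines, plus the analysis steps the demo app
# walks backwards through — control-based normalisation, four-parameter
# logistic (4PL) dose-response fits, an area-based drug sensitivity score and
# the drug-drug score correlation matrix.

.plate_rows <- 8L
.plate_cols <- 12L

#' Generate a synthetic drug screen
#'
#' One 96-well plate (8 x 12) per cell line. Columns 1..11 hold the sample
#' wells (drugs x concentrations, row-major); the last column holds three
#' negative (vehicle, viability 1) and three positive (full-kill, viability
#' 0) control wells, with any leftover wells empty. True 4PL parameters are
#' drawn per (drug, cell line): drugs belong to latent mechanism clusters,
#' and a cluster shares a per-cell-line sensitivity profile, so drug
#' sensitivity scores correlate within clusters across cell lines. The raw
#' signal is `plate scale x viability` plus Gaussian noise, with an optional
#' additive edge artifact on border wells.
#'
#' @param n_drugs,n_cell_lines,n_conc design dimensions (defaults 12, 8, 7).
#' @param n_clusters number of latent drug-mechanism clusters (default 3).
#' @param noise_sd Gaussian noise sd on the viability scale (default 0.05).
#' @param edge_effect additive artifact on border wells, viability scale
#'   (default 0).
#' @param seed RNG seed.
#' @return A `drug_screen`: list with `wells` (long data frame: cell_line,
#'   row, col, role, drug, conc_idx, conc, true_viability, signal),
#'   `conc` (tested concentrations, strictly increasing, uM),
#'   `truth` (data frame of true 4PL parameters per drug x cell line with
#'   cluster labels) and `plate_scale` (per cell line).
#' @export
gen_drug_screen <- function(n_drugs = 12L, n_cell_lines = 8L, n_conc = 7L,
                            n_clusters = 3L, noise_sd = 0.05,
                            edge_effect = 0, seed = 1L) {
  stopifnot(n_drugs >= 2L, n_cell_lines >= 3L, n_conc >= 4L, n_clusters >= 1L)
  set.seed(seed)
  n_ctrl <- 6L
  sample_capacity <- .plate_rows * .plate_cols - .plate_rows  # last column reserved
  needed <- n_drugs * n_conc
  if (needed > sample_capacity) {
    stop(sprintf("plate overflow: %d sample wells needed, %d available",
                 needed, sample_capacity), call. = FALSE)
  }
  conc <- 10^seq(log10(0.001), log10(10), length.out = n_conc)  # uM

  cluster <- rep_len(seq_len(n_clusters), n_drugs)
  # per-cluster, per-cell-line latent sensitivity; shared within a cluster
  sens <- matrix(stats::rnorm(n_clusters * n_cell_lines), n_clusters)
  drug_c0 <- stats::runif(n_drugs, log10(min(conc)) + 1, log10(max(conc)) - 1)

  truth <- expand.grid(drug = seq_len(n_drugs), cell_line = seq_len(n_cell_lines))
  resp <- stats::plogis(2 * sens[cbind(cluster[truth$drug], truth$cell_line)] +
                          stats::rnorm(nrow(truth), 0, 0.3))
  truth$cluster <- cluster[truth$drug]
  truth$a <- 1
  truth$d <- 1 - 0.9 * resp
  truth$c0 <- 10^(drug_c0[truth$drug] + stats::rnorm(nrow(truth), 0, 0.15))
  truth$b <- stats::runif(nrow(truth), 1, 3)

  plate_scale <- stats::rlnorm(n_cell_lines, log(5e4), 0.1)

  wells <- vector("list", n_cell_lines)
  for (l in seq_len(n_cell_lines)) {
    role <- matrix("empty", .plate_rows, .plate_cols)
    drug <- matrix(NA_integer_, .plate_rows, .plate_cols)
    ci <- matrix(NA_integer_, .plate_rows, .plate_cols)
    # sample wells row-major over columns 1..(ncol-1)
    k <- 0L
    for (r in seq_len(.plate_rows)) {
      for (cc in seq_len(.plate_cols - 1L)) {
        k <- k + 1L
        if (k <= needed) {
          role[r, cc] <- "sample"
          drug[r, cc] <- (k - 1L) %/% n_conc + 1L
          ci[r, cc] <- (k - 1L) %% n_conc + 1L
        }
      }
    }
    role[1:3, .plate_cols] <- "negative"
    role[4:6, .plate_cols] <- "positive"

    tv <- matrix(NA_real_, .plate_rows, .plate_cols)
    for (r in seq_len(.plate_rows)) {
      for (cc in seq_len(.plate_cols)) {
        tv[r, cc] <- switch(role[r, cc],
          sample = {
            pr <- truth[truth$drug == drug[r, cc] & truth$cell_line == l, ]
            fourpl(conc[ci[r, cc]], pr$a, pr$d, pr$c0, pr$b)
          },
          negative = 1, positive = 0, empty = NA_real_)
      }
    }
    edge <- outer(seq_len(.plate_rows) %in% c(1L, .plate_rows),
                  seq_len(.plate_cols) %in% c(1L, .plate_cols), "|")
    sig <- plate_scale[l] *
      (tv + edge_effect * edge + stats::rnorm(length(tv), 0, noise_sd))
    sig[role == "empty"] <- plate_scale[l] *
      stats::rnorm(sum(role == "empty"), 0.02, noise_sd)

    wells[[l]] <- data.frame(
      cell_line = l,
      row = rep(seq_len(.plate_rows), times = .plate_cols),
      col = rep(seq_len(.plate_cols), each = .plate_rows),
      role = as.vector(role), drug = as.vector(drug),
      conc_idx = as.vector(ci),
      conc = conc[as.vector(ci)],
      true_viability = as.vector(tv),
      signal = as.vector(sig),
      stringsAsFactors = FALSE)
  }
  structure(list(wells = do.call(rbind, wells), conc = conc, truth = truth,
                 plate_scale = plate_scale,
                 dims = c(drugs = n_drugs, cell_lines = n_cell_lines,
                          conc = n_conc)),
            class = "drug_screen")
}

#' @export
print.drug_screen <- function(x, ...) {
  cat(sprintf("<drug screen: %d drugs x %d cell lines x %d concentrations, %d wells>\n",
              x$dims["drugs"], x$dims["cell_lines"], x$dims["conc"],
              nrow(x$wells)))
  invisible(x)
}

#' The four-parameter logistic curve
#'
#' `f(c) = d + (a - d) / (1 + (c / c0)^b)`: viability `a` at zero dose,
#' `d` at saturating dose, inflection at `c0` (where `f = (a + d)/2`), slope
#' `b`.
#'
#' @param conc concentrations (> 0).
#' @param a,d,c0,b curve parameters.
#' @return Numeric vector of the same length as `conc`.
#' @export
fourpl <- function(conc, a, d, c0, b) {
  d + (a - d) / (1 + (conc / c0)^b)
}

#' Normalise raw plate signals to viability fractions
#'
#' Anchored to the on-plate controls:
#' `viability = (signal - mean(positive)) / (mean(negative) - mean(positive))`,
#' clipped to `[-0.1, 1.5]`, so vehicle wells sit at 1 and full-kill wells at 0.
#'
#' @param plate a long well table for one plate (rows of a
#'   [gen_drug_screen()] `wells` data frame for one cell line), with columns
#'   `role` and `signal`; needs at least one negative and one positive
#'   control well.
#' @return The sample-well rows of `plate` with a `viability` column added.
#' @export
normalize_viability <- function(plate) {
  neg <- plate$signal[plate$role == "negative"]
  pos <- plate$signal[plate$role == "positive"]
  if (!length(neg) || !length(pos)) {
    stop("plate needs at least one negative and one positive control well",
         call. = FALSE)
  }
  if (mean(neg) == mean(pos)) stop("degenerate controls", call. = FALSE)
  out <- plate[plate$role == "sample", , drop = FALSE]
  out$viability <- pmin(pmax((out$signal - mean(pos)) / (mean(neg) - mean(pos)),
                             -0.1), 1.5)
  out
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Bounded least squares over `a` in 0.5..1.5, `d` in -0.1..1.0, `c0` within
#' the tested concentration range widened 100-fold each way, and `b` in
#' 0.1..10 (`c0` and `b` optimised on the log scale). Starts from `a = 1`,
#' `d = 0`, `c0 =` the geometric mean of the concentrations, `b = 1`, with a
#' small multi-start over slopes and inflections to avoid local optima. Flat
#' data (viability variance below 1e-6) short-circuits to the flat model
#' `a = d = mean(viability)`.
#'
#' @param conc tested concentrations (>= 4 distinct values, > 0).
#' @param viability viability fractions, same length as `conc`.
#' @return A `sigmoid_fit`: list(a, d, c0, b, rss, converged).
#' @export
fit_4pl <- function(conc, viability) {
  stopifnot(length(conc) == length(viability))
  ok <- is.finite(conc) & is.finite(viability)
  conc <- conc[ok]; viability <- viability[ok]
  if (length(unique(conc)) < 4L) {
    stop("need at least 4 distinct concentrations", call. = FALSE)
  }
  if (stats::var(viability) < 1e-6) {
    m <- mean(viability)
    return(structure(list(a = m, d = m, c0 = exp(mean(log(conc))), b = 1,
                          rss = sum((viability - m)^2), converged = TRUE),
                     class = "sigmoid_fit"))
  }
  lc <- log(conc)
  lower <- c(0.5, -0.1, log(min(conc) * 0.01), log(0.1))
  upper <- c(1.5, 1.0, log(max(conc) * 100), log(10))
  # par = (a, d, log c0, log b); (c/c0)^b = exp(b * (log c - log c0))
  obj <- function(par) {
    f <- par[2] + (par[1] - par[2]) / (1 + exp(exp(par[4]) * (lc - par[3])))
    sum((viability - f)^2)
  }
  runs <- list()
  for (b0 in c(0.5, 1, 2, 4)) {
    for (lc0 in unique(c(mean(lc), stats::quantile(lc, c(0.25, 0.75),
                                                   names = FALSE)))) {
      start <- c(1, 0, lc0, log(b0))
      fit <- tryCatch(
        stats::optim(start, obj, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(factr = 1e4, maxit = 500L)),
        error = function(e) NULL)
      if (!is.null(fit)) runs[[length(runs) + 1L]] <- fit
    }
  }
  best <- NULL
  if (length(runs)) {
    vals <- vapply(runs, `[[`, 0, "value")
    # among (near-)optimal starts prefer one with a clean convergence code
    near <- which(vals <= min(vals) * (1 + 1e-6) + 1e-12)
    clean <- near[vapply(runs[near], function(r) r$convergence == 0L, TRUE)]
    best <- runs[[if (length(clean)) clean[1] else which.min(vals)]]
  }
  if (is.null(best)) {
    return(structure(list(a = NA_real_, d = NA_real_, c0 = NA_real_,
                          b = NA_real_, rss = NA_real_, converged = FALSE),
                     class = "sigmoid_fit"))
  }
  structure(list(a = best$par[1], d = best$par[2], c0 = exp(best$par[3]),
                 b = exp(best$par[4]), rss = best$value,
                 converged = best$convergence == 0L),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<4PL fit: a=%.3f d=%.3f c0=%.4g b=%.3f rss=%.4g%s>\n",
              x$a, x$d, x$c0, x$b, x$rss,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Area-based drug sensitivity score
#'
#' The mean over log10-concentration of the inhibition `max(0, 1 - f(c))`
#' across the tested range (trapezoid rule on 101 log-spaced points): the
#' normalised area of inhibition. 0 means no inhibition anywhere in the
#' range, 1 complete kill everywhere.
#'
#' @param fit a converged [fit_4pl()] result.
#' @param conc_range numeric pair of positive concentrations.
#' @return A score in `[0, 1]`.
#' @export
drug_score <- function(fit, conc_range) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  stopifnot(length(conc_range) == 2L, all(conc_range > 0),
            conc_range[1] < conc_range[2])
  lg <- seq(log10(conc_range[1]), log10(conc_range[2]), length.out = 101L)
  inh <- pmax(0, 1 - fourpl(10^lg, fit$a, fit$d, fit$c0, fit$b))
  h <- diff(lg)
  sum((inh[-1] + inh[-length(inh)]) / 2 * h) / (lg[101] - lg[1])
}

#' Drug-drug Pearson correlation of sensitivity scores
#'
#' @param scores drugs x cell-lines score matrix (>= 3 cell lines).
#' @return drugs x drugs symmetric Pearson matrix, unit diagonal; a
#'   zero-variance drug yields missing entries.
#' @export
score_correlation <- function(scores) {
  stopifnot(is.matrix(scores), ncol(scores) >= 3L)
  res <- suppressWarnings(stats::cor(t(scores)))
  v <- apply(scores, 1L, stats::var)
  diag(res) <- ifelse(v > 0, 1, NA_real_)
  res
}

# Full reduction: plates -> viabilities -> fits -> scores (drugs x cell lines)
screen_scores <- function(screen) {
  nd <- screen$dims[["drugs"]]; nl <- screen$dims[["cell_lines"]]
  fits <- vector("list", nd * nl)
  dim(fits) <- c(nd, nl)
  scores <- matrix(NA_real_, nd, nl)
  viab <- vector("list", nl)
  rng <- range(screen$conc)
  for (l in seq_len(nl)) {
    v <- normalize_viability(screen$wells[screen$wells$cell_line == l, ])
    viab[[l]] <- v
    for (dr in seq_len(nd)) {
      vd <- v[v$drug == dr, ]
      ft <- fit_4pl(vd$conc, vd$viability)
      fits[[dr, l]] <- ft
      if (isTRUE(ft$converged)) scores[dr, l] <- drug_score(ft, rng)
    }
  }
  list(fits = fits, scores = scores, viability = viab)
}
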