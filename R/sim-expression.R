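# Synthetic paired tumor/normal expression data and the small differential
# expression summary used by the demo apps. The generator emulates a paired
# oral-cancer design: a few tissue samples per patient, negative-binomial
# counts with gene-wise log-normal base means, mean-dependent dispersion and
# log-normal library sizes, and a minority of truly differential genes with
# symmetric log2 effects in the tumor samples.

#' Generate a synthetic paired expression dataset
#'
#' Counts are negative binomial with gene-wise base means (CPM scale) drawn
#' log-normally, dispersion `0.05 + 1/mean`, and library sizes log-normal
#' (sdlog 0.3) around two million reads. A fraction `frac_de` of genes is
#' truly differentially expressed: their tumor samples receive a log2 effect
#' drawn from Normal(0, `effect_sd`). Fully reproducible from `seed`.
#'
#' @param n_genes number of genes (default 8000).
#' @param n_patients number of patients; each contributes one sample per
#'   condition (default 17).
#' @param frac_de fraction of truly DE genes in `[0, 1]`.
#' @param effect_sd standard deviation of the true log2 effects.
#' @param conditions condition labels; the first is the reference (normal),
#'   effects are applied to the second (tumor). A third label (dysplasia) may
#'   be added; it behaves like the reference.
#' @param seed RNG seed.
#' @return An `expression_dataset`: list with `counts` (genes x samples
#'   integer matrix), `samples` (data frame: sample, patient, condition),
#'   `lib_sizes` (observed column sums) and `truth` (data frame: gene, is_de,
#'   log2_effect).
#' @examples
#' d <- gen_expression(n_genes = 100, n_patients = 4, seed = 1)
#' dim(d$counts)  # 100 x 8
#' @export
gen_expression <- function(n_genes = 8000L, n_patients = 17L, frac_de = 0.1,
                           effect_sd = 2, conditions = c("normal", "tumor"),
                           seed = 1L) {
  if (frac_de < 0 || frac_de > 1) stop("frac_de must be in [0, 1]", call. = FALSE)
  stopifnot(n_genes >= 1L, n_patients >= 2L, length(conditions) >= 2L)
  set.seed(seed)
  n_cond <- length(conditions)
  n_samples <- n_patients * n_cond
  samples <- data.frame(
    sample = paste0("P", rep(seq_len(n_patients), each = n_cond), "_",
                    rep(conditions, n_patients)),
    patient = paste0("P", rep(seq_len(n_patients), each = n_cond)),
    condition = rep(conditions, n_patients),
    stringsAsFactors = FALSE)

  base_cpm <- stats::rlnorm(n_genes, meanlog = 3, sdlog = 1.6)
  lib <- stats::rlnorm(n_samples, meanlog = log(2e6), sdlog = 0.3)
  n_de <- round(frac_de * n_genes)
  is_de <- rep(FALSE, n_genes)
  if (n_de > 0) is_de[sample.int(n_genes, n_de)] <- TRUE
  effect <- ifelse(is_de, stats::rnorm(n_genes, 0, effect_sd), 0)

  tumor <- samples$condition == conditions[2L]
  mu <- outer(base_cpm, lib / 1e6)
  mu[, tumor] <- mu[, tumor] * 2^effect
  disp <- 0.05 + 1 / mu
  counts <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu, size = 1 / disp),
                   nrow = n_genes,
                   dimnames = list(paste0("gene", seq_len(n_genes)),
                                   samples$sample))
  storage.mode(counts) <- "integer"
  # the generator's true sequencing depths; observed column sums differ from
  # these by sampling noise and by the composition shift the DE genes induce
  # in the tumor samples
  structure(list(counts = counts, samples = samples,
                 lib_sizes = stats::setNames(lib, samples$sample),
                 truth = data.frame(gene = rownames(counts), is_de = is_de,
                                    log2_effect = effect,
                                    stringsAsFactors = FALSE)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression dataset: %d genes x %d samples, %d patients, %d DE genes>\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$patient)), sum(x$truth$is_de)))
  invisible(x)
}

#' Counts per million
#'
#' @param counts genes x samples count matrix.
#' @param lib_sizes library size per sample (defaults to column sums; must be
#'   strictly positive).
#' @param log return `log2(CPM + pseudocount)` instead of CPM.
#' @param pseudocount added before the log (default 1, so a zero count maps
#'   to log-CPM 0).
#' @return A numeric matrix with the dimensions of `counts`.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts), log = FALSE,
                pseudocount = 1) {
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0", call. = FALSE)
  out <- sweep(counts, 2L, lib_sizes, "/") * 1e6
  if (log) out <- log2(out + pseudocount)
  out
}

#' Three-value differential expression summary for a paired design
#'
#' Summarises each gene to average expression, log2 fold change and a
#' p-value: `aveExpr` is the row mean of log2-CPM over all samples, `log2FC`
#' the mean over patients of the within-patient (tumor - normal) log2-CPM
#' difference, and `p` a two-sided paired t-test on those differences
#' (`p = 1` when all differences are identical). `adj_p` is the
#' Benjamini-Hochberg adjustment.
#'
#' CPM values are computed against the dataset's library sizes (for the
#' synthetic generator, the true sequencing depths). Normalising by observed
#' column sums instead would fold the composition shift induced by strongly
#' DE genes into every null gene's fold change; composition-robust scale
#' estimation (TMM, median-of-ratios) is deliberately out of scope here.
#'
#' @param dataset an [gen_expression()] result (or a compatible list); every
#'   patient must have exactly one sample of each of the two conditions
#'   being compared (the first two levels of the sample table's conditions).
#' @param pseudocount passed to [cpm()].
#' @return A data frame: gene, aveExpr, log2FC, p, adj_p.
#' @export
de_summary <- function(dataset, pseudocount = 1) {
  counts <- dataset$counts
  samples <- dataset$samples
  conds <- unique(samples$condition)[1:2]
  lib <- dataset$lib_sizes %||% colSums(counts)
  lcpm <- cpm(counts, lib_sizes = lib, log = TRUE, pseudocount = pseudocount)
  patients <- unique(samples$patient)
  norm_idx <- integer(length(patients)); tum_idx <- integer(length(patients))
  for (i in seq_along(patients)) {
    ni <- which(samples$patient == patients[i] & samples$condition == conds[1])
    ti <- which(samples$patient == patients[i] & samples$condition == conds[2])
    if (length(ni) != 1L || length(ti) != 1L) {
      stop(sprintf("patient %s is not paired (needs one '%s' and one '%s' sample)",
                   patients[i], conds[1], conds[2]), call. = FALSE)
    }
    norm_idx[i] <- ni; tum_idx[i] <- ti
  }
  d <- lcpm[, tum_idx, drop = FALSE] - lcpm[, norm_idx, drop = FALSE]
  n <- length(patients)
  md <- rowMeans(d)
  sdd <- sqrt(rowSums((d - md)^2) / (n - 1))
  tstat <- md / (sdd / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  p[sdd == 0] <- 1   # zero-variance differences carry no evidence
  data.frame(gene = rownames(counts) %||% paste0("gene", seq_len(nrow(counts))),
             aveExpr = rowMeans(lcpm), log2FC = md, p = p,
             adj_p = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Significance colors for an MA plot
#'
#' Genes with adjusted p-value strictly below `alpha` get the significant
#' color; all others the default color.
#'
#' @param result a [de_summary()] data frame.
#' @param alpha adjusted-p threshold in (0, 1); default 0.1.
#' @param sig_color,other_color the two colors.
#' @return Character vector of colors, one per gene.
#' @export
significance_colors <- function(result, alpha = 0.1,
                                sig_color = "#d62728", other_color = "#555555") {
  stopifnot(alpha > 0, alpha <= 1)
  ifelse(result$adj_p < alpha, sig_color, other_color)
}

#' Sample-sample Spearman correlation matrix
#'
#' Spearman correlation (Pearson correlation of mid-ranks, average ranks for
#' ties) between every pair of sample columns. A zero-variance sample yields
#' missing correlations (and a missing diagonal entry) rather than an error.
#'
#' @param expr genes x samples numeric matrix with >= 2 genes.
#' @return A samples x samples symmetric matrix with unit diagonal.
#' @export
spearman_matrix <- function(expr) {
  stopifnot(is.matrix(expr), nrow(expr) >= 2L)
  res <- suppressWarnings(stats::cor(expr, method = "spearman"))
  v <- apply(expr, 2L, function(col) stats::var(rank(col)))
  diag(res) <- ifelse(v > 0, 1, NA_real_)
  res
}

#' Subset a dataset to randomly selected genes
#'
#' Uniform sampling without replacement, keeping the original row order and
#' subsetting the truth table consistently.
#'
#' @param dataset an [gen_expression()] result.
#' @param n_keep number of genes to keep (default 8000).
#' @param seed RNG seed.
#' @return An `expression_dataset` with `n_keep` genes.
#' @export
subset_genes <- function(dataset, n_keep = 8000L, seed = 1L) {
  n <- nrow(dataset$counts)
  if (n_keep > n) {
    stop(sprintf("n_keep (%d) exceeds the number of genes (%d)", n_keep, n),
         call. = FALSE)
  }
  set.seed(seed)
  keep <- sort(sample.int(n, n_keep))
  out <- dataset
  out$counts <- dataset$counts[keep, , drop = FALSE]
  out$truth <- dataset$truth[keep, , drop = FALSE]
  out
}
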