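# Expression generator and the paired differential-expression summary.

test_that("the expression generator honors its design contract", {
  d <- gen_expression(n_genes = 200, n_patients = 5, frac_de = 0.2, seed = 3)
  expect_equal(dim(d$counts), c(200L, 10L))
  expect_true(all(d$counts >= 0))
  expect_type(d$counts[1, 1], "integer")
  expect_equal(nrow(d$samples), 10L)
  expect_equal(length(unique(d$samples$patient)), 5L)
  expect_equal(sum(d$truth$is_de), 40L)
  expect_true(all(d$truth$log2_effect[!d$truth$is_de] == 0))
  # pairing: every patient has one sample per condition
  tab <- table(d$samples$patient, d$samples$condition)
  expect_true(all(tab == 1L))
  # purity: same seed, same data
  d2 <- gen_expression(n_genes = 200, n_patients = 5, frac_de = 0.2, seed = 3)
  expect_identical(d$counts, d2$counts)
  expect_identical(d$truth, d2$truth)
  # no DE genes when frac_de = 0
  d0 <- gen_expression(n_genes = 50, n_patients = 3, frac_de = 0, seed = 1)
  expect_equal(sum(d0$truth$is_de), 0L)
  expect_error(gen_expression(frac_de = 2), "frac_de")
})

test_that("cpm scales by library size and handles the log transform", {
  counts <- matrix(c(5L, 995L, 20L, 80L), 2)
  expect_equal(cpm(matrix(5L), lib_sizes = 1000)[1, 1], 5000)
  expect_equal(unname(colSums(cpm(counts))), c(1e6, 1e6))
  expect_equal(cpm(matrix(0L), lib_sizes = 10, log = TRUE)[1, 1], 0)
  expect_error(cpm(counts, lib_sizes = c(0, 1)), "> 0")
})

test_that("de_summary recovers a constructed two-fold change", {
  # tumor counts exactly 2x normal, equal library sizes, large counts
  n_pat <- 6L
  normal <- matrix(4000L, 3, n_pat)
  tumor <- normal * 2L
  counts <- matrix(0L, 3, 2 * n_pat)
  counts[, seq(1, 2 * n_pat, 2)] <- normal
  counts[, seq(2, 2 * n_pat, 2)] <- tumor
  ds <- list(counts = counts,
             samples = data.frame(
               sample = paste0("s", 1:(2 * n_pat)),
               patient = rep(paste0("P", 1:n_pat), each = 2),
               condition = rep(c("normal", "tumor"), n_pat)),
             lib_sizes = rep(1e6, 2 * n_pat))
  r <- de_summary(ds)
  expect_equal(r$log2FC, rep(1, 3), tolerance = 0.01)
  # all differences identical -> zero variance -> p = 1
  expect_equal(r$p, rep(1, 3))
  # unpaired designs error naming the patient
  ds_bad <- ds
  ds_bad$samples$condition[2] <- "normal"
  expect_error(de_summary(ds_bad), "patient P1")
})

test_that("de_summary p-values match stats::t.test gene by gene", {
  d <- gen_expression(n_genes = 30, n_patients = 8, frac_de = 0.3, seed = 5)
  r <- de_summary(d)
  lcpm <- cpm(d$counts, d$lib_sizes, log = TRUE)
  tum <- which(d$samples$condition == "tumor")
  nor <- which(d$samples$condition == "normal")
  for (g in c(1L, 7L, 30L)) {
    ref <- t.test(lcpm[g, tum], lcpm[g, nor], paired = TRUE)
    expect_equal(r$p[g], ref$p.value, tolerance = 1e-12)
    expect_equal(r$log2FC[g], unname(ref$estimate), tolerance = 1e-12)
  }
  expect_true(all(r$adj_p >= r$p))
  expect_true(all(r$p >= 0 & r$p <= 1))
})

test_that("BH adjustment matches the step-up oracle", {
  p <- c(0.01, 0.02, 0.04)
  expect_equal(p.adjust(p, "BH"), c(0.03, 0.03, 0.04))
  expect_equal(oracle_bh(p), c(0.03, 0.03, 0.04))
  set.seed(8)
  pr <- runif(200)^2
  expect_equal(p.adjust(pr, "BH"), oracle_bh(pr), tolerance = 1e-12)
})

test_that("significance coloring uses a strict threshold", {
  r <- data.frame(adj_p = c(0.05, 0.1, 0.2, 1))
  cols <- significance_colors(r, alpha = 0.1, sig_color = "S", other_color = "N")
  expect_identical(cols, c("S", "N", "N", "N"))  # 0.1 itself is not significant
  expect_identical(significance_colors(data.frame(adj_p = rep(1, 4)),
                                       sig_color = "S", other_color = "N"),
                   rep("N", 4))
  all_sig <- significance_colors(data.frame(adj_p = c(0.5, 1)), alpha = 1,
                                 sig_color = "S", other_color = "N")
  expect_identical(all_sig, c("S", "N"))
})

test_that("spearman_matrix equals the rank-then-Pearson oracle", {
  x <- c(1, 2, 3); y <- c(10, 20, 15)
  m <- cbind(a = x, b = y)
  s <- spearman_matrix(m)
  expect_equal(s["a", "b"], 0.5)
  expect_equal(s["a", "b"], oracle_spearman(x, y))
  # invariance under monotone transforms; exact unit diagonal
  m2 <- cbind(x = x, ex = exp(x))
  s2 <- spearman_matrix(m2)
  expect_identical(s2["x", "ex"], 1)
  expect_identical(unname(diag(s2)), c(1, 1))
  # ties use mid-ranks
  xt <- c(1, 1, 2, 3); yt <- c(2, 2, 2, 5)
  expect_equal(spearman_matrix(cbind(xt, yt))["xt", "yt"],
               oracle_spearman(xt, yt))
  # zero-variance sample -> missing, not an error
  s3 <- spearman_matrix(cbind(a = c(1, 2, 3), flat = c(2, 2, 2)))
  expect_true(is.na(s3["a", "flat"]))
})

test_that("subset_genes samples without replacement, preserving order", {
  d <- gen_expression(n_genes = 100, n_patients = 3, seed = 2)
  s1 <- subset_genes(d, 40, seed = 9)
  expect_equal(nrow(s1$counts), 40L)
  expect_identical(rownames(s1$counts), s1$truth$gene)
  expect_false(anyDuplicated(rownames(s1$counts)) > 0)
  # order preserved: kept rows appear in original order
  expect_false(is.unsorted(match(rownames(s1$counts), rownames(d$counts))))
  expect_identical(subset_genes(d, 40, seed = 9)$counts, s1$counts)
  full <- subset_genes(d, 100, seed = 1)
  expect_identical(full$counts, d$counts)
  expect_error(subset_genes(d, 101), "exceeds")
})
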