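test_that("low-expression filter uses a strict count and sample-fraction rule", {
  n <- 100
  samples <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    condition = rep(c("tumor", "normal"), n / 2),
    pair_id = rep(sprintf("P%03d", seq_len(n / 2)), each = 2)
  )
  counts <- rbind(
    keep_boundary = c(rep(11, 5), rep(0, n - 5)),   # 11 in exactly 5 = ceil(0.05*100)
    drop_equal = rep(10, n),                        # exactly 10 everywhere: strict >
    drop_few = c(rep(100, 4), rep(0, n - 4))        # only 4 samples
  )
  expr <- expression_set(counts, samples)
  f <- filter_low_expression(expr, min_count = 10, min_frac = 0.05)
  expect_identical(rownames(f$counts), "keep_boundary")

  # min_frac = 0 keeps any gene exceeding the count somewhere
  f0 <- filter_low_expression(expr, min_count = 10, min_frac = 0)
  expect_setequal(rownames(f0$counts), c("keep_boundary", "drop_few"))

  # idempotence
  expect_identical(filter_low_expression(f)$counts, f$counts)
})

test_that("connectivity QC handles identical samples and -Inf threshold", {
  counts <- matrix(rep(c(5, 50, 500, 20), 4), ncol = 4)
  rownames(counts) <- paste0("G", 1:4)
  samples <- tibble::tibble(sample_id = paste0("S", 1:4),
                            condition = "tumor", pair_id = paste0("S", 1:4))
  expr <- expression_set(counts, samples)
  res <- sample_qc_connectivity(expr)
  expect_true(all(res$qc$z == 0))  # sd = 0 -> Z defined as 0
  expect_length(res$removed, 0)

  set.seed(2)
  expr2 <- make_paired_expression(50, 5)
  res2 <- sample_qc_connectivity(expr2, z_thresh = -Inf)
  expect_length(res2$removed, 0)
  expect_error(sample_qc_connectivity(
    expression_set(counts[, 1:2], samples[1:2, ])), "at least 3")
})

test_that("an anti-correlated sample is removed, matching a brute-force oracle", {
  set.seed(8)
  n_genes <- 200
  base <- rlnorm(n_genes, 5, 1)
  counts <- sapply(1:9, function(i) rpois(n_genes, base))
  outlier <- rpois(n_genes, rev(base))  # reversed profile: anti-correlated
  counts <- cbind(counts, outlier)
  rownames(counts) <- sprintf("G%03d", seq_len(n_genes))
  samples <- tibble::tibble(sample_id = sprintf("S%02d", 1:10),
                            condition = "tumor", pair_id = sprintf("S%02d", 1:10))
  res <- sample_qc_connectivity(expression_set(counts, samples))
  expect_identical(res$removed, "S10")

  # brute-force connectivity oracle
  lc <- log2(counts + 1)
  conn_oracle <- vapply(1:10, function(i) {
    sum(vapply(setdiff(1:10, i), function(j) cor(lc[, i], lc[, j]), 0))
  }, 0)
  expect_equal(unname(res$qc$connectivity), conn_oracle, tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(21)
  counts <- matrix(rnbinom(600, mu = 80, size = 5), ncol = 6) + 1
  expect_equal(
    unname(size_factors(counts)),
    unname(DESeq2::estimateSizeFactorsForMatrix(counts)),
    tolerance = 1e-8
  )
})

test_that("paired DE recovers a planted 4-fold increase", {
  set.seed(31)
  lfc <- c(rep(2, 10), rep(0, 90))
  expr <- make_paired_expression(100, 20, lfc = lfc)
  de <- differential_expression(expr)
  planted <- de[1:10, ]
  expect_true(all(planted$status == "up"))
  expect_true(all(abs(planted$lfc - 2) <= 0.3))
  expect_true(mean(de$status[11:100] == "unchanged") > 0.95)
})

test_that("identical tumor and normal columns yield only unchanged calls", {
  set.seed(32)
  counts_half <- matrix(rnbinom(50 * 5, mu = 100, size = 10), ncol = 5)
  counts <- cbind(counts_half, counts_half)
  rownames(counts) <- sprintf("G%03d", 1:50)
  samples <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:10),
    condition = rep(c("tumor", "normal"), each = 5),
    pair_id = rep(sprintf("P%02d", 1:5), 2)
  )
  de <- differential_expression(expression_set(counts, samples))
  expect_true(all(de$status == "unchanged"))
  expect_true(all(de$lfc == 0))
})

test_that("a significant gene below the LFC gate stays unchanged", {
  set.seed(33)
  # consistent 2^0.8-fold increase in 10 genes: tiny p, lfc ~ 0.8 < 1
  lfc <- c(rep(0.8, 10), rep(0, 50))
  expr <- make_paired_expression(60, 30, lfc = lfc, dispersion = 0.01)
  de <- differential_expression(expr)
  strong <- de[de$q_value < 0.01 & de$lfc < 1 & de$lfc > 0.5, ]
  expect_gt(nrow(strong), 0)
  expect_true(all(strong$status == "unchanged"))
})

test_that("DE errors on unpaired designs and too few pairs", {
  expr <- make_paired_expression(10, 3)
  broken <- expr
  broken$samples$pair_id[1] <- "PX"
  expect_error(differential_expression(broken), "matched normal")
  expect_error(
    differential_expression(make_paired_expression(10, 2)), "3 pairs"
  )
})

test_that("DE on null data keeps the called fraction at or below the FDR", {
  set.seed(34)
  calls <- 0L
  genes <- 0L
  for (r in 1:50) {
    expr <- make_paired_expression(80, 10, lfc = 0, dispersion = 0.2)
    de <- differential_expression(expr)
    calls <- calls + sum(de$status != "unchanged")
    genes <- genes + nrow(de)
  }
  rate <- calls / genes
  mc_se <- sqrt(0.05 * 0.95 / genes)
  expect_lte(rate, 0.05 + 3 * mc_se)
})

test_that("homeobox classification partitions the supplied list", {
  de <- tibble::tibble(
    gene_id = c("H1", "H2", "H3", "G1"),
    status = c("up", "down", "unchanged", "up")
  )
  cls <- classify_homeobox(de, c("H1", "H2", "H3"))
  expect_equal(cls$class[cls$gene_id == "H1"], "aHBG")
  expect_equal(cls$class[cls$gene_id == "H2"], "uHBG")
  expect_equal(cls$class[cls$gene_id == "H3"], "uHBG")  # no change -> uHBG
  expect_false("G1" %in% cls$gene_id)

  expect_warning(classify_homeobox(de, c("H1", "NOPE")), "absent")
  expect_error(classify_homeobox(de, character()), "empty")

  # partition property on random DE tables
  set.seed(41)
  for (i in 1:20) {
    rde <- tibble::tibble(
      gene_id = sprintf("R%02d", 1:30),
      status = sample(c("up", "down", "unchanged"), 30, TRUE)
    )
    hb <- sample(rde$gene_id, 12)
    cl <- classify_homeobox(rde, hb)
    a <- cl$gene_id[cl$class == "aHBG"]
    u <- cl$gene_id[cl$class == "uHBG"]
    expect_length(intersect(a, u), 0)
    expect_setequal(c(a, u), hb)
  }
})
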