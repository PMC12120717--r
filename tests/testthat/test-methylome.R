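test_that("coverage filter masks at the >= threshold boundary", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(101L, 151L, 201L, 251L, 301L))
  samples <- tibble::tibble(sample_id = "S1", condition = "normal", pair_id = "P1")
  total <- matrix(c(4L, 3L, 10L, 2L, 4L), ncol = 1)
  meth <- matrix(c(2L, 1L, 5L, 1L, 2L), ncol = 1)
  m <- methylome(sites, meth, total, samples)

  f <- filter_by_coverage(m, min_cov = 4)
  expect_equal(nrow(f$sites), 3L)  # coverages 4, 10, 4 retained
  expect_equal(f$sites$pos, c(101L, 201L, 301L))

  expect_identical(filter_by_coverage(m, min_cov = 0), m)
  expect_warning(f0 <- filter_by_coverage(m, min_cov = 100), "below the coverage")
  expect_equal(nrow(f0$sites), 0L)
})

test_that("region mean methylation averages per-site betas unweighted", {
  m <- methylome_from_beta(matrix(c(0.0, 0.2, 0.4), ncol = 1))
  expect_equal(region_mean_methylation(m, "chr1", 0, 1000), 0.2)
  m1 <- methylome_from_beta(matrix(0.3, 1, 1))
  expect_equal(region_mean_methylation(m1, "chr1", 0, 1000), 0.3)
  expect_error(region_mean_methylation(m1, "chr1", 5000, 6000), "no covered CpG")
})

test_that("UMR caller recovers a planted low-methylation run exactly", {
  beta <- matrix(c(rep(0.8, 10), rep(0.05, 20), rep(0.8, 10)), ncol = 1)
  m <- methylome_from_beta(beta)
  umrs <- call_umrs(m, umr_max_meth = 0.10, umr_min_cpgs = 10)
  expect_equal(nrow(umrs), 1L)
  expect_equal(umrs$n_cpgs, 20L)
  # spans first to last low CpG: sites 11..30 -> pos 601..1551
  expect_equal(umrs$start, 600L)
  expect_equal(umrs$end, 1551L)
  expect_lt(umrs$mean_meth, 0.10)

  expect_equal(nrow(call_umrs(methylome_from_beta(matrix(0.8, 40, 1)))), 0L)
  expect_equal(nrow(call_umrs(m, umr_min_cpgs = 30)), 0L)
})

test_that("UMR runs break at large gaps and chromosome boundaries", {
  # 24 low CpGs, but a 5 kb gap after the 12th
  pos <- c(seq(101L, by = 50L, length.out = 12),
           seq(6101L, by = 50L, length.out = 12))
  m <- methylome_from_beta(matrix(0.05, 24, 1), pos = pos)
  umrs <- call_umrs(m, umr_min_cpgs = 10, max_gap_bp = 1000)
  expect_equal(nrow(umrs), 2L)
  expect_equal(umrs$n_cpgs, c(12L, 12L))
})

test_that("UMR recovery on piecewise-constant methylomes has Jaccard >= 0.9", {
  set.seed(42)
  # 3 planted low segments of 20 CpGs in a high background, binomial noise
  truth_runs <- list(21:40, 81:100, 141:160)
  bt <- rep(0.8, 200)
  for (r in truth_runs) bt[r] <- 0.05
  m <- make_paired_methylome(200, 4, bt, bt, coverage = 30)
  umrs <- call_umrs(m, umr_min_cpgs = 15)
  pos <- m$sites$pos
  planted <- purrr::map_dfr(truth_runs, function(r) {
    tibble::tibble(chrom = "chr1", start = pos[r[1]] - 1L, end = pos[r[length(r)]])
  })
  expect_gte(interval_jaccard(umrs, planted), 0.9)
})

test_that("DMR caller flags a maximally separated region as hyper", {
  set.seed(11)
  m <- make_paired_methylome(15, 10, beta_tumor = 0.9, beta_normal = 0.1,
                             coverage = 30)
  dmrs <- call_dmrs(m)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$direction, "hyper")
  expect_equal(dmrs$mean_diff, 0.8, tolerance = 0.05)
  expect_lt(dmrs$q_value, 0.05)
  expect_equal(dmrs$n_cpgs, 15L)
})

test_that("DMR caller enforces the effect-size threshold regardless of p", {
  set.seed(12)
  # highly significant but tiny separation: |mean_diff| = 0.05 < 0.1
  m <- make_paired_methylome(30, 20, beta_tumor = 0.55, beta_normal = 0.50,
                             coverage = 200)
  dmrs <- call_dmrs(m, min_diff = 0.1)
  expect_equal(nrow(dmrs), 0L)
})

test_that("DMR caller errors without pairing metadata", {
  m <- make_paired_methylome(15, 3, 0.9, 0.1)
  m$samples$pair_id <- paste0("X", seq_len(6))  # breaks the pairing
  expect_error(call_dmrs(m), "pairing")
})

test_that("DMR detection is monotone in the planted difference", {
  deltas <- c(0.1, 0.2, 0.4)
  hits <- vapply(deltas, function(d) {
    set.seed(99)
    m <- make_paired_methylome(60, 8, beta_tumor = 0.2 + d, beta_normal = 0.2,
                               coverage = 30)
    nrow(call_dmrs(m))
  }, numeric(1))
  expect_true(all(diff(hits) >= 0))
})

test_that("DMR summary counts, fractions and degenerate cases", {
  dmrs <- tibble::tibble(direction = c(rep("hyper", 5), rep("hypo", 5)))
  s <- summarize_dmrs(dmrs)
  expect_equal(s$hypo_fraction, 50.0)
  expect_equal(s$fold_ratio, 1)
  expect_equal(s$n_hyper + s$n_hypo, nrow(dmrs))  # conservation

  s0 <- summarize_dmrs(tibble::tibble(direction = character()))
  expect_true(is.na(s0$hypo_fraction))
  expect_true(is.na(s0$fold_ratio))
})

test_that("context annotation follows promoter > gene body > intergenic", {
  gm <- simple_gene_models()
  regions <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr1"),
    start = c(200L, 2000L, 100000L, 14050L),
    end = c(300L, 2100L, 100100L, 14100L)
  )
  ann <- annotate_context(regions, gm)
  # GA is + with tss 1000: promoter [(-500) -> 0, 1500); region [200,300) inside
  expect_equal(ann$context[1], "promoter")
  expect_equal(ann$gene_id[1], "GA")
  # [2000,2100) inside GA body, outside its promoter
  expect_equal(ann$context[2], "gene_body")
  expect_equal(ann$gene_id[2], "GA")
  expect_equal(ann$context[3], "intergenic")
  expect_true(is.na(ann$gene_id[3]))
  # GB is - with tss 13999: promoter [13500, 15500) on the upstream side
  expect_equal(ann$context[4], "promoter")
  expect_equal(ann$gene_id[4], "GB")
})

test_that("every region receives exactly one context label", {
  set.seed(5)
  gm <- simple_gene_models()
  regions <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 50, TRUE),
    start = sample.int(20000L, 50)
  ) |> dplyr::mutate(end = start + sample.int(500L, 50))
  ann <- annotate_context(regions, gm)
  expect_equal(nrow(ann), 50L)
  expect_true(all(ann$context %in% c("promoter", "gene_body", "intergenic")))
  expect_true(all(!is.na(ann$gene_id) | ann$context == "intergenic"))
})

test_that("gene-body profile is constant on a constant field", {
  gm <- simple_gene_models()[1, ]
  m <- methylome_from_beta(matrix(0.5, 40, 1),
                           pos = seq(1026L, by = 100L, length.out = 40))
  prof <- gene_body_profile(m, gm, n_bins = 10)
  expect_equal(nrow(prof), 10L)
  expect_true(all(abs(prof$mean_meth - 0.5) < 1e-12, na.rm = TRUE))
})

test_that("minus-strand profile is the reverse of the plus-strand profile", {
  gm_plus <- simple_gene_models()[1, ]
  gm_minus <- gm_plus
  gm_minus$strand <- "-"
  gm_minus$tss <- gm_minus$end - 1L
  set.seed(3)
  betas <- matrix(runif(40), ncol = 1)
  m <- methylome_from_beta(betas, pos = seq(1026L, by = 100L, length.out = 40))
  p_plus <- gene_body_profile(m, gm_plus, n_bins = 20)
  p_minus <- gene_body_profile(m, gm_minus, n_bins = 20)
  expect_equal(p_minus$mean_meth, rev(p_plus$mean_meth))
})

test_that("a single CpG lands in exactly one profile bin", {
  gm <- simple_gene_models()[1, ]  # [1000, 5000), +
  # CpG at 10% of the body: 0-based 1400 -> 1-based 1401
  m <- methylome_from_beta(matrix(0.3, 1, 1), pos = 1401L)
  prof <- gene_body_profile(m, gm, n_bins = 10)
  expect_equal(sum(!is.na(prof$mean_meth)), 1L)
  expect_equal(prof$mean_meth[prof$bin == 1], 0.3)
  expect_error(gene_body_profile(m, gm, n_bins = 0), "n_bins")
})
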