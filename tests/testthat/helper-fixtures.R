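# in-code fixtures shared across test files

# paired methylome with constant tumor/normal means plus binomial noise;
# CpGs every `spacing` bp on one chromosome
make_paired_methylome <- function(n_sites, n_pairs, beta_tumor, beta_normal,
                                  coverage = 20, spacing = 50, chrom = "chr1",
                                  start_pos = 101L) {
  pos <- seq(start_pos, by = spacing, length.out = n_sites)
  samples <- tibble::tibble(
    sample_id = c(sprintf("T%02d", seq_len(n_pairs)),
                  sprintf("N%02d", seq_len(n_pairs))),
    condition = rep(c("tumor", "normal"), each = n_pairs),
    pair_id = rep(sprintf("P%02d", seq_len(n_pairs)), 2)
  )
  bt <- rep(beta_tumor, length.out = n_sites)
  bn <- rep(beta_normal, length.out = n_sites)
  total <- matrix(coverage, n_sites, 2 * n_pairs)
  mu <- cbind(matrix(bt, n_sites, n_pairs), matrix(bn, n_sites, n_pairs))
  meth <- matrix(rbinom(length(mu), coverage, as.vector(mu)), n_sites)
  methylome(tibble::tibble(chrom = chrom, pos = pos), meth, total, samples)
}

# deterministic methylome from explicit beta matrix (coverage 10, exact
# counts round(beta * 10))
methylome_from_beta <- function(beta_mat, pos = NULL, chrom = "chr1",
                                samples = NULL) {
  n_sites <- nrow(beta_mat)
  n_smp <- ncol(beta_mat)
  if (is.null(pos)) pos <- seq(101L, by = 50L, length.out = n_sites)
  if (is.null(samples)) {
    samples <- tibble::tibble(
      sample_id = sprintf("S%02d", seq_len(n_smp)),
      condition = rep("normal", n_smp),
      pair_id = sprintf("P%02d", seq_len(n_smp))
    )
  }
  total <- matrix(10L, n_sites, n_smp)
  meth <- round(beta_mat * 10)
  methylome(tibble::tibble(chrom = chrom, pos = pos), meth, total, samples)
}

simple_gene_models <- function() {
  validate_gene_models(tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 10000L, 2000L),
    end = c(5000L, 14000L, 6000L),
    gene_id = c("GA", "GB", "GC"),
    score = 0L,
    strand = c("+", "-", "+")
  ))
}

# paired expression set with per-gene fold changes (tumor mean = base * 2^lfc)
make_paired_expression <- function(n_genes, n_pairs, lfc = 0, base_mean = 100,
                                   dispersion = 0.05) {
  lfc <- rep(lfc, length.out = n_genes)
  samples <- tibble::tibble(
    sample_id = c(sprintf("T%02d", seq_len(n_pairs)),
                  sprintf("N%02d", seq_len(n_pairs))),
    condition = rep(c("tumor", "normal"), each = n_pairs),
    pair_id = rep(sprintf("P%02d", seq_len(n_pairs)), 2)
  )
  mu <- cbind(
    matrix(base_mean * 2^lfc, n_genes, n_pairs),
    matrix(base_mean, n_genes, n_pairs)
  )
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
                   n_genes)
  rownames(counts) <- sprintf("G%03d", seq_len(n_genes))
  expression_set(counts, samples)
}

# memoised default synthetic benchmark (shared by recovery tests); the
# bundle and pipeline report are expensive, so build them once per run
.bench_cache <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.bench_cache$bundle)) {
    .bench_cache$bundle <- generate_bundle(synthetic_config(seed = 1))
  }
  .bench_cache$bundle
}

default_report <- function() {
  if (is.null(.bench_cache$report)) {
    .bench_cache$report <- suppressWarnings(run_pipeline(default_bundle()))
  }
  .bench_cache$report
}
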