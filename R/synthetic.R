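#' Configuration for the synthetic multi-omics generator
#'
#' Defines the study conditions the generator emulates: paired
#' tumor/normal methylomes in which every homeobox-like gene carries a
#' gene-body UMR that is unmethylated in normal tissue, with planted
#' driver genes whose UMRs gain methylation in tumors while the genes
#' are simultaneously overexpressed; plus consistent variant allele
#' frequencies, interaction-network degrees, missense-constraint scores
#' and survival structure tied to a per-sample axis activity.
#'
#' Per driver, a multiplier `u ~ Uniform(0.6, 1.4)` couples the planted
#' methylation gain (`delta_meth * u`), expression change
#' (`driver_lfc * u`) and constraint score, so that driver-level
#' methylation and expression changes co-vary as they do in tumors where
#' gene-body UMR hypermethylation accompanies activation.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_pairs tumor/normal sample pairs (default 30).
#' @param n_drivers planted activated driver genes (default 40).
#' @param n_homeobox genes in the homeobox-like superset containing the
#'   drivers (default 170).
#' @param gene_length,intergenic_gap gene body length and intergenic
#'   spacing in bp (defaults 2000 / 3000).
#' @param cpg_spacing_genic,cpg_spacing_intergenic CpG spacing inside
#'   gene bodies and between genes (defaults 50 / 500 bp).
#' @param umr_frac fraction of the gene body covered by the planted UMR,
#'   centered in the body (default 0.4).
#' @param beta_low methylation level inside normal-tissue UMRs
#'   (default 0.05).
#' @param beta_high background methylation level (default 0.8).
#' @param delta_meth planted tumor methylation gain inside driver UMRs
#'   (default 0.3).
#' @param driver_lfc planted driver log2 fold change (default 2).
#' @param beta_precision beta-binomial precision of per-site methylation
#'   (default 30).
#' @param mean_coverage mean CpG read coverage, Poisson (default 30).
#' @param low_coverage_frac fraction of observations drawn at low
#'   coverage (mean 2) so the coverage filter has work to do
#'   (default 0.05).
#' @param nb_dispersion negative-binomial dispersion of counts
#'   (default 0.15).
#' @param expr_meanlog,expr_sdlog log-normal baseline expression means
#'   (defaults `log(200)` / 1).
#' @param snv_per_kb,snv_per_kb_driver somatic SNV densities (defaults
#'   1 / 2 per kb).
#' @param maf_scale driver allele-frequency inflation factor (default 3).
#' @param edge_prob_driver,edge_prob_background per-partner edge
#'   probabilities in the interaction network (defaults 0.06 / 0.006).
#' @param activity_coef log2 expression shift of axis genes per unit of
#'   sample activity (default 0.5).
#' @param n_axis_genes drivers forming the survival regulatory axis
#'   (default 5).
#' @param survival_baseline_hazard baseline hazard per month
#'   (default 0.02).
#' @param hazard_ratio_per_activity hazard multiplier per unit activity
#'   (default 2).
#' @param follow_up_months administrative censoring horizon (default 60).
#' @param seed root seed; independent substreams are derived from it per
#'   data type (default 1).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000, n_pairs = 30, n_drivers = 40,
                             n_homeobox = 170, gene_length = 2000,
                             intergenic_gap = 3000, cpg_spacing_genic = 50,
                             cpg_spacing_intergenic = 500, umr_frac = 0.4,
                             beta_low = 0.05, beta_high = 0.8,
                             delta_meth = 0.3, driver_lfc = 2,
                             beta_precision = 30, mean_coverage = 30,
                             low_coverage_frac = 0.05, nb_dispersion = 0.15,
                             expr_meanlog = log(200), expr_sdlog = 1,
                             snv_per_kb = 1, snv_per_kb_driver = 2,
                             maf_scale = 3, edge_prob_driver = 0.06,
                             edge_prob_background = 0.006,
                             activity_coef = 0.5, n_axis_genes = 5,
                             survival_baseline_hazard = 0.02,
                             hazard_ratio_per_activity = 2,
                             follow_up_months = 60, seed = 1) {
  cfg <- as.list(environment())
  if (!(cfg$n_drivers <= cfg$n_homeobox && cfg$n_homeobox <= cfg$n_genes)) {
    abort("need n_drivers <= n_homeobox <= n_genes")
  }
  probs <- c(cfg$beta_low, cfg$beta_high, cfg$umr_frac, cfg$low_coverage_frac,
             cfg$edge_prob_driver, cfg$edge_prob_background)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (cfg$delta_meth + cfg$beta_low > 1) abort("delta_meth + beta_low must be <= 1")
  if (cfg$delta_meth < 0) abort("delta_meth must be >= 0")
  if (cfg$n_pairs < 2) abort("need at least 2 tumor/normal pairs")
  if (cfg$seed < 0 || cfg$seed > 2^30) abort("seed must lie in [0, 2^30]")
  if (cfg$n_axis_genes > max(cfg$n_drivers, 1)) {
    abort("n_axis_genes must not exceed n_drivers")
  }
  structure(cfg, class = "synthetic_config")
}

# substream seed derivation: one independent stream per data type so
# regenerating one block leaves the others identical
sub_seed <- function(cfg, k) as.integer((cfg$seed * 37 + k) %% 2^30)

# beta-binomial draw, vectorized
rbetabinom <- function(n, size, mu, precision) {
  p <- rbeta(n, mu * precision, (1 - mu) * precision)
  rbinom(n, size, p)
}

#' Generate a synthetic multi-omics bundle with known ground truth
#'
#' Produces, from a single root seed, every input the pipeline consumes:
#' gene models, a paired tumor/normal methylome with planted gene-body
#' UMRs (hypermethylated in tumors for driver genes), a paired
#' expression matrix with overexpressed drivers, variant records with
#' driver-inflated allele frequencies and a C>T-at-CpG-dominated
#' spectrum, an interaction edge list with driver-biased connectivity,
#' missense-constraint Z scores correlated with driver status, and
#' survival times whose hazard increases with a per-sample axis
#' activity that also shifts the expression of the axis genes.
#'
#' @param config a [synthetic_config()].
#' @param dir optional directory; when given, every table is written in
#'   the formats the package readers consume (plus `truth_genes.tsv`,
#'   `truth_samples.tsv` and `config.yaml`).
#' @return A list (class `synthetic_bundle`) with elements
#'   `gene_models`, `methylome`, `expression`, `variants`, `edges`,
#'   `missense_z`, `homeobox_ids`, `survival`, `truth` (list `genes`,
#'   `samples`, `umrs`, `axis_genes`) and `config`.
#' @export
generate_bundle <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config

  ## --- gene layout and planted effects ------------------------------
  set.seed(sub_seed(cfg, 1))
  n_chrom <- 4L
  chrom <- paste0("chr", ((seq_len(cfg$n_genes) - 1L) %% n_chrom) + 1L)
  idx_on_chrom <- stats::ave(seq_len(cfg$n_genes), chrom, FUN = seq_along)
  pitch <- cfg$gene_length + cfg$intergenic_gap
  start <- as.integer((idx_on_chrom - 1L) * pitch + cfg$intergenic_gap)
  gene_models <- tibble(
    chrom = chrom,
    start = start,
    end = as.integer(start + cfg$gene_length),
    gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
    score = 0L,
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  ) %>% validate_gene_models()

  hbg_idx <- sample.int(cfg$n_genes, cfg$n_homeobox)
  driver_idx <- sample(hbg_idx, cfg$n_drivers)
  is_hbg <- seq_len(cfg$n_genes) %in% hbg_idx
  is_driver <- seq_len(cfg$n_genes) %in% driver_idx
  u <- ifelse(is_driver, runif(cfg$n_genes, 0.6, 1.4), 0)
  delta_i <- ifelse(is_driver, pmin(cfg$delta_meth * u, 1 - cfg$beta_low), 0)
  lfc_i <- ifelse(is_driver, cfg$driver_lfc * u, 0)
  axis_genes <- gene_models$gene_id[sort(driver_idx)[seq_len(cfg$n_axis_genes)]]

  umr_half <- cfg$gene_length * cfg$umr_frac / 2
  umr_start <- ifelse(is_hbg,
                      as.integer(gene_models$start + cfg$gene_length / 2 - umr_half),
                      NA_integer_)
  umr_end <- ifelse(is_hbg,
                    as.integer(gene_models$start + cfg$gene_length / 2 + umr_half),
                    NA_integer_)

  samples <- tibble(
    sample_id = c(sprintf("T%03d", seq_len(cfg$n_pairs)),
                  sprintf("N%03d", seq_len(cfg$n_pairs))),
    condition = rep(c("tumor", "normal"), each = cfg$n_pairs),
    pair_id = rep(sprintf("P%03d", seq_len(cfg$n_pairs)), 2)
  )

  ## --- methylome ----------------------------------------------------
  set.seed(sub_seed(cfg, 2))
  sites <- purrr::map_dfr(unique(gene_models$chrom), function(ch) {
    gm <- gene_models[gene_models$chrom == ch, ]
    chrom_end <- max(gm$end) + cfg$intergenic_gap
    genic <- purrr::map_dfr(seq_len(nrow(gm)), function(i) {
      offs <- seq(25L, cfg$gene_length - 1L, by = cfg$cpg_spacing_genic)
      tibble(pos = gm$start[i] + offs + 1L)  # 1-based CpG point
    })
    inter <- tibble(pos = seq(1L, chrom_end, by = cfg$cpg_spacing_intergenic))
    inter <- inter[!overlaps_any(inter$pos - 1L, gm$start, gm$end), , drop = FALSE]
    tibble(chrom = ch, pos = sort(unique(c(genic$pos, inter$pos))))
  }) %>% arrange(chrom, pos)

  n_sites <- nrow(sites)
  mu_normal <- rep(cfg$beta_high, n_sites)
  mu_tumor <- rep(cfg$beta_high, n_sites)
  for (i in which(is_hbg)) {
    in_umr <- sites$chrom == gene_models$chrom[i] &
      (sites$pos - 1L) >= umr_start[i] & (sites$pos - 1L) < umr_end[i]
    mu_normal[in_umr] <- cfg$beta_low
    mu_tumor[in_umr] <- cfg$beta_low + delta_i[i]
  }
  n_cells <- n_sites * nrow(samples)
  low <- runif(n_cells) < cfg$low_coverage_frac
  cov <- integer(n_cells)
  cov[!low] <- rpois(sum(!low), cfg$mean_coverage)
  cov[low] <- rpois(sum(low), 2)
  cov <- pmax(cov, 1L)
  mu_mat <- cbind(
    matrix(rep(mu_tumor, cfg$n_pairs), n_sites),
    matrix(rep(mu_normal, cfg$n_pairs), n_sites)
  )
  meth <- matrix(
    rbetabinom(n_cells, cov, as.vector(mu_mat), cfg$beta_precision),
    n_sites
  )
  meth_obj <- methylome(sites, meth, matrix(cov, n_sites), samples)

  ## --- expression ----------------------------------------------------
  set.seed(sub_seed(cfg, 3))
  activity <- rnorm(cfg$n_pairs)
  base_mu <- rlnorm(cfg$n_genes, cfg$expr_meanlog, cfg$expr_sdlog)
  sf <- rlnorm(nrow(samples), 0, 0.1)
  lfc_mat <- matrix(0, cfg$n_genes, nrow(samples))
  lfc_mat[, seq_len(cfg$n_pairs)] <- lfc_i  # tumor columns
  ax <- match(axis_genes, gene_models$gene_id)
  lfc_mat[ax, seq_len(cfg$n_pairs)] <- lfc_mat[ax, seq_len(cfg$n_pairs)] +
    cfg$activity_coef * rep(activity, each = length(ax))
  mu_expr <- (base_mu * 2^lfc_mat) * rep(sf, each = cfg$n_genes)
  counts <- matrix(
    stats::rnbinom(length(mu_expr), mu = as.vector(mu_expr),
                   size = 1 / cfg$nb_dispersion),
    cfg$n_genes
  )
  rownames(counts) <- gene_models$gene_id
  expr <- expression_set(counts, samples)

  ## --- variants -------------------------------------------------------
  set.seed(sub_seed(cfg, 4))
  rate <- ifelse(is_driver, cfg$snv_per_kb_driver, cfg$snv_per_kb)
  n_var <- rpois(cfg$n_genes, rate * cfg$gene_length / 1000)
  gidx <- rep(seq_len(cfg$n_genes), n_var)
  total_var <- length(gidx)
  variants <- if (total_var == 0) {
    tibble(chrom = character(), pos = integer(), ref = character(),
           alt = character(), af = double(), context = character())
  } else {
    pos <- gene_models$start[gidx] +
      sample.int(cfg$gene_length, total_var, replace = TRUE)  # 1-based inside body
    af <- rbeta(total_var, 2, 200)
    af <- ifelse(is_driver[gidx], pmin(af * cfg$maf_scale, 0.5), af)
    classes <- c("C>T", "C>A", "C>G", "T>A", "T>C", "T>G")
    cls <- sample(classes, total_var, replace = TRUE,
                  prob = c(0.6, 0.08, 0.08, 0.08, 0.08, 0.08))
    ref <- substr(cls, 1, 1)
    alt <- substr(cls, 3, 3)
    at_cpg <- ref == "C" & runif(total_var) < 0.75
    plus3 <- ifelse(at_cpg, "G", sample(c("A", "C", "T"), total_var, replace = TRUE))
    minus1 <- sample(c("A", "C", "G", "T"), total_var, replace = TRUE)
    ctx <- paste0(minus1, ref, plus3)
    # present roughly half the purine-strand way to exercise collapsing
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    flip <- runif(total_var) < 0.5
    rc <- function(s) vapply(strsplit(s, ""), function(b) {
      paste(rev(unname(comp[b])), collapse = "")
    }, "")
    tibble(
      chrom = gene_models$chrom[gidx],
      pos = as.integer(pos),
      ref = ifelse(flip, unname(comp[ref]), ref),
      alt = ifelse(flip, unname(comp[alt]), alt),
      af = af,
      context = ifelse(flip, rc(ctx), ctx)
    ) %>% arrange(chrom, pos)
  }
  variants <- validate_variants(variants)

  ## --- interaction edges ---------------------------------------------
  set.seed(sub_seed(cfg, 5))
  p_edge <- ifelse(is_driver, cfg$edge_prob_driver, cfg$edge_prob_background)
  n_out <- rbinom(cfg$n_genes, cfg$n_genes - 1L, p_edge)
  src <- rep(seq_len(cfg$n_genes), n_out)
  dst <- unlist(purrr::map(seq_len(cfg$n_genes), function(i) {
    if (n_out[i] == 0) return(integer())
    sample(setdiff(seq_len(cfg$n_genes), i), n_out[i])
  }))
  edges <- tibble(
    gene_a = gene_models$gene_id[src],
    gene_b = gene_models$gene_id[dst],
    combined_score = sample(400:1000, length(src), replace = TRUE)
  )

  ## --- missense constraint -------------------------------------------
  set.seed(sub_seed(cfg, 6))
  missense_z <- tibble(
    gene_id = gene_models$gene_id,
    missense_z = ifelse(is_driver, 3.0 + u + rnorm(cfg$n_genes, 0, 0.3),
                        rnorm(cfg$n_genes))
  )

  ## --- survival --------------------------------------------------------
  set.seed(sub_seed(cfg, 7))
  hazard <- cfg$survival_baseline_hazard *
    cfg$hazard_ratio_per_activity^activity
  t_event <- rexp(cfg$n_pairs, rate = hazard)
  t_cens <- runif(cfg$n_pairs, cfg$follow_up_months / 2, cfg$follow_up_months)
  survival <- tibble(
    sample_id = samples$sample_id[seq_len(cfg$n_pairs)],
    time = pmax(pmin(t_event, t_cens), 1e-3),
    event = as.integer(t_event <= t_cens)
  )

  truth <- list(
    genes = tibble(
      gene_id = gene_models$gene_id,
      is_homeobox = is_hbg,
      is_driver = is_driver,
      umr_start = umr_start,
      umr_end = umr_end,
      delta_meth = delta_i,
      lfc = lfc_i
    ),
    samples = tibble(
      sample_id = samples$sample_id[seq_len(cfg$n_pairs)],
      activity = activity
    ),
    umrs = tibble(
      chrom = gene_models$chrom[is_hbg],
      start = umr_start[is_hbg],
      end = umr_end[is_hbg],
      gene_id = gene_models$gene_id[is_hbg]
    ) %>% arrange(chrom, start),
    axis_genes = axis_genes
  )

  bundle <- structure(
    list(
      gene_models = gene_models, methylome = meth_obj, expression = expr,
      variants = variants, edges = edges, missense_z = missense_z,
      homeobox_ids = gene_models$gene_id[is_hbg], survival = survival,
      truth = truth, config = cfg
    ),
    class = "synthetic_bundle"
  )
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

overlaps_any <- function(pos0, starts, ends) {
  if (!length(starts)) return(rep(FALSE, length(pos0)))
  idx <- findInterval(pos0, starts)
  idx > 0 & pos0 < ends[pmax(idx, 1)]
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "<synthetic_bundle> %d genes (%d homeobox, %d drivers), %d pairs, %d CpGs, seed %d\n",
    x$config$n_genes, x$config$n_homeobox, x$config$n_drivers,
    x$config$n_pairs, nrow(x$methylome$sites), x$config$seed
  ))
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gene_models(bundle$gene_models, p("gene_models.tsv"))
  write_methylome(bundle$methylome, p("methylome.tsv.gz"))
  write_expression(bundle$expression, p("expression.tsv.gz"))
  readr::write_tsv(bundle$variants, p("variants.tsv"))
  readr::write_tsv(bundle$edges, p("edges.tsv"))
  readr::write_tsv(bundle$missense_z, p("missense_z.tsv"))
  readr::write_tsv(bundle$methylome$samples, p("samples.tsv"))
  readr::write_tsv(bundle$survival, p("survival.tsv"))
  readr::write_tsv(bundle$truth$genes, p("truth_genes.tsv"))
  readr::write_tsv(bundle$truth$samples, p("truth_samples.tsv"))
  writeLines(bundle$homeobox_ids, p("homeobox_ids.txt"))
  yaml::write_yaml(unclass(bundle$config), p("config.yaml"))
  invisible(dir)
}

#' Base-pair Jaccard index of two interval sets
#'
#' Overlap divided by union, in base pairs, after collapsing each set.
#'
#' @param a,b tibbles with `chrom`, `start`, `end` (0-based half-open).
#' @return A number in `[0, 1]` (`NA` when both sets are empty).
#' @export
interval_jaccard <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) return(NA_real_)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  gr_a <- GenomicRanges::reduce(regions_to_granges(a))
  gr_b <- GenomicRanges::reduce(regions_to_granges(b))
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(gr_a, gr_b)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(gr_a, gr_b)))
  inter / uni
}

#' Driver-recovery report against the planted truth
#'
#' @param truth the `truth` element of a `synthetic_bundle`.
#' @param top_genes character vector of pipeline-ranked gene ids (best
#'   first), e.g. `rank_and_select(fit, k)$gene_id`.
#' @param called_umrs optional tibble of called UMRs for a base-pair
#'   Jaccard against the planted UMRs.
#' @param k evaluation depth (default: length of `top_genes`).
#' @return One-row tibble `k, n_drivers, n_hit, precision_at_k,
#'   recall_at_k, umr_jaccard`.
#' @export
truth_report <- function(truth, top_genes, called_umrs = NULL, k = length(top_genes)) {
  drivers <- truth$genes$gene_id[truth$genes$is_driver]
  unknown <- setdiff(top_genes, truth$genes$gene_id)
  if (length(unknown)) {
    abort(paste0("ranked gene ids absent from truth: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  topk <- head(top_genes, k)
  hit <- length(intersect(topk, drivers))
  tibble(
    k = k,
    n_drivers = length(drivers),
    n_hit = hit,
    precision_at_k = if (k > 0) hit / k else NA_real_,
    recall_at_k = if (length(drivers) > 0) hit / length(drivers) else NA_real_,
    umr_jaccard = if (is.null(called_umrs)) NA_real_ else {
      interval_jaccard(called_umrs, truth$umrs)
    }
  )
}

#' Simulate the activity-survival benchmark
#'
#' A lightweight proportional-hazards generator for the survival axis:
#' per-sample activities `a ~ N(0, 1)` shift the expression of a small
#' axis gene set (`mean x 2^(activity_coef * a)`, negative-binomial
#' counts) and multiply the exponential hazard by
#' `hazard_ratio^a`, with uniform administrative censoring.
#'
#' @param n_samples number of patients (default 200).
#' @param n_axis_genes genes in the axis set (default 5).
#' @param n_noise_genes unrelated background genes included so the
#'   expression object is not degenerate (default 20).
#' @param activity_coef log2 expression shift per unit activity
#'   (default 1).
#' @param hazard_ratio hazard multiplier per unit activity (default 2).
#' @param baseline_hazard events per month at activity 0 (default 0.02).
#' @param follow_up_months censoring horizon (default 60).
#' @param base_mean,dispersion negative-binomial count parameters
#'   (defaults 200 / 0.15).
#' @param seed integer seed.
#' @return list `expression` ([expression_set()]), `survival` (tibble),
#'   `axis_genes`, `activity` (tibble `sample_id, activity`).
#' @export
simulate_activity_survival <- function(n_samples = 200, n_axis_genes = 5,
                                       n_noise_genes = 20, activity_coef = 1,
                                       hazard_ratio = 2, baseline_hazard = 0.02,
                                       follow_up_months = 60, base_mean = 200,
                                       dispersion = 0.15, seed = 1) {
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n_samples))
  a <- rnorm(n_samples)
  axis_genes <- sprintf("AX%02d", seq_len(n_axis_genes))
  noise_genes <- sprintf("NG%02d", seq_len(n_noise_genes))
  mu_axis <- outer(rep(base_mean, n_axis_genes), 2^(activity_coef * a))
  mu_noise <- matrix(base_mean, n_noise_genes, n_samples)
  mu <- rbind(mu_axis, mu_noise)
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = 1 / dispersion), nrow(mu))
  rownames(counts) <- c(axis_genes, noise_genes)
  expr <- expression_set(
    counts,
    tibble(sample_id = ids, condition = "tumor", pair_id = ids)
  )
  hz <- baseline_hazard * hazard_ratio^a
  t_event <- rexp(n_samples, rate = hz)
  t_cens <- runif(n_samples, follow_up_months / 2, follow_up_months)
  list(
    expression = expr,
    survival = tibble(
      sample_id = ids,
      time = pmax(pmin(t_event, t_cens), 1e-3),
      event = as.integer(t_event <= t_cens)
    ),
    axis_genes = axis_genes,
    activity = tibble(sample_id = ids, activity = a)
  )
}
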