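#' Run the full discovery pipeline on a data bundle
#'
#' Chains every stage end-to-end: CpG coverage filtering, UMR calling on
#' the normal samples, tumor-vs-normal DMR calling and genomic-context
#' annotation, expression filtering / connectivity QC / paired
#' differential expression, activated (aHBG) vs unactivated (uHBG)
#' homeobox classification, methylation-expression integration
#' (gene-body-UMR delta correlation per gene set, hypergeometric overlap
#' of aHBGs with hypermethylated genes, SNV densities, substitution
#' spectrum), Gene Risk Score ranking, and — when a survival table is
#' present — pathway-activity survival stratification.
#'
#' @param bundle a `synthetic_bundle` from [generate_bundle()], or any
#'   list with the same elements (`gene_models`, `methylome`,
#'   `expression`, `variants`, `edges`, `missense_z`, `homeobox_ids`,
#'   optional `survival`) built from files via the `read_*` readers.
#' @param out_dir optional directory; when given every intermediate
#'   table is written as TSV (with a version/seed/parameter-hash header
#'   comment) along with a `params.yaml` snapshot.
#' @param min_cov CpG coverage threshold (default 4).
#' @param umr_max_meth,umr_min_cpgs UMR definition (defaults 0.10 / 10).
#' @param dmr_min_diff,dmr_min_cpgs,dmr_fdr DMR thresholds (defaults
#'   0.1 / 10 / 0.05).
#' @param de_lfc,de_fdr differential-expression thresholds (defaults
#'   1 / 0.05).
#' @param grs_k GRS genes to report (default 15).
#' @param axis_genes survival-axis gene set; default `NULL` uses the
#'   top 5 GRS genes.
#' @param min_prop minimum group proportion for the survival cutpoint
#'   (default 0.1).
#' @param seed recorded in output headers (default 1; the pipeline
#'   itself is deterministic given its inputs).
#' @return A list of class `pipeline_report` with elements `umrs`,
#'   `dmrs`, `dmr_summary`, `dmr_context`, `de`, `qc`, `homeobox`,
#'   `delta_umr`, `correlations`, `overlap`, `snv`, `spectrum`,
#'   `grs` (a `grs_fit`), `grs_top`, `survival` (an `activity_result`
#'   or `NULL`), and `params`.
#' @export
run_pipeline <- function(bundle, out_dir = NULL, min_cov = 4,
                         umr_max_meth = 0.10, umr_min_cpgs = 10,
                         dmr_min_diff = 0.1, dmr_min_cpgs = 10,
                         dmr_fdr = 0.05, de_lfc = 1, de_fdr = 0.05,
                         grs_k = 15, axis_genes = NULL, min_prop = 0.1,
                         seed = 1) {
  params <- list(
    min_cov = min_cov, umr_max_meth = umr_max_meth,
    umr_min_cpgs = umr_min_cpgs, dmr_min_diff = dmr_min_diff,
    dmr_min_cpgs = dmr_min_cpgs, dmr_fdr = dmr_fdr, de_lfc = de_lfc,
    de_fdr = de_fdr, grs_k = grs_k, min_prop = min_prop, seed = seed
  )
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(tbl, name) {
    if (!is.null(out_dir)) write_output_table(tbl, file.path(out_dir, name), params)
    tbl
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  ## methylome stages
  m <- stage("coverage_filter", filter_by_coverage(bundle$methylome, min_cov))
  normals <- m$samples$sample_id[m$samples$condition == "normal"]
  umrs <- stage("umr_calling", call_umrs(
    m, samples = normals, umr_max_meth = umr_max_meth,
    umr_min_cpgs = umr_min_cpgs
  ))
  emit(umrs, "umrs.tsv")
  dmrs <- stage("dmr_calling", call_dmrs(
    m, min_diff = dmr_min_diff, min_cpgs = dmr_min_cpgs, fdr = dmr_fdr
  ))
  emit(dmrs, "dmrs.tsv")
  dmr_summary <- emit(summarize_dmrs(dmrs), "dmr_summary.tsv")
  dmr_context <- stage("context_annotation",
                       annotate_context(dmrs, bundle$gene_models))
  emit(dmr_context, "dmr_context.tsv")

  ## expression stages
  expr_f <- stage("expression_filter", filter_low_expression(bundle$expression))
  qc <- stage("sample_qc", sample_qc_connectivity(expr_f))
  expr_qc <- qc$expression
  # keep only complete tumor/normal pairs after QC
  keep_pairs <- expr_qc$samples %>%
    count(.data$pair_id) %>%
    filter(.data$n == 2) %>%
    pull(.data$pair_id)
  meta_p <- expr_qc$samples[expr_qc$samples$pair_id %in% keep_pairs, ]
  expr_p <- expression_set(expr_qc$counts[, meta_p$sample_id, drop = FALSE], meta_p)
  de <- stage("differential_expression",
              differential_expression(expr_p, lfc_cut = de_lfc, fdr = de_fdr))
  emit(de, "de_table.tsv")
  homeobox <- stage("homeobox_classification",
                    classify_homeobox(de, bundle$homeobox_ids))
  emit(homeobox, "homeobox_classes.tsv")
  ahbg <- homeobox$gene_id[homeobox$class == "aHBG"]
  uhbg <- homeobox$gene_id[homeobox$class == "uHBG"]

  ## integration stages
  delta_umr <- stage("gene_body_umr_delta", gene_region_delta(
    m, bundle$gene_models, region_class = "gene_body_umr", umrs = umrs
  ))
  delta_tbl <- delta_umr %>% inner_join(select(de, "gene_id", "lfc"), by = "gene_id")
  emit(delta_tbl, "gene_body_umr_delta.tsv")
  corr_for <- function(genes) {
    tryCatch(methylation_expression_correlation(delta_tbl, genes),
             error = function(e) tibble(rho = NA_real_, p_value = NA_real_, n = 0L))
  }
  correlations <- bind_rows(
    mutate(corr_for(NULL), gene_set = "all"),
    mutate(corr_for(ahbg), gene_set = "aHBG"),
    mutate(corr_for(uhbg), gene_set = "uHBG")
  )
  emit(correlations, "meth_expr_correlations.tsv")

  hyper_genes <- dmr_context %>%
    filter(.data$direction == "hyper", !is.na(.data$gene_id)) %>%
    pull(.data$gene_id) %>% unique()
  universe <- de$gene_id
  overlap <- stage("overlap_enrichment", overlap_enrichment(
    intersect(ahbg, universe), intersect(hyper_genes, universe), universe
  ))
  emit(overlap, "ahbg_hyper_overlap.tsv")

  snv <- stage("snv_density", snv_density(
    bundle$variants,
    bundle$gene_models %>% filter(.data$gene_id %in% c(ahbg, uhbg))
  ) %>% mutate(class = ifelse(.data$gene_id %in% ahbg, "aHBG", "uHBG")))
  emit(snv, "snv_density.tsv")
  spectrum <- stage("substitution_spectrum", substitution_spectrum(bundle$variants))
  emit(spectrum, "substitution_spectrum.tsv")

  ## gene risk score
  connectivity <- stage("network_connectivity",
                        network_connectivity(bundle$edges, universe))
  maf <- stage("gene_maf", gene_maf(bundle$variants, bundle$gene_models))
  features <- stage("grs_features", assemble_grs_features(
    de, delta_umr, maf, connectivity, bundle$missense_z
  ))
  emit(features, "grs_features.tsv")
  grs <- stage("grs", compute_grs(features))
  emit(tidy(grs), "grs_scores.tsv")
  grs_top <- rank_and_select(grs, k = min(grs_k, nrow(grs$scores)))
  emit(grs_top, "grs_top.tsv")
  if (!is.null(out_dir)) {
    writeLines(
      paste(names(grs$weights), signif(grs$weights, 6), sep = "\t"),
      file.path(out_dir, "grs_weights.txt")
    )
  }

  ## survival axis (optional)
  surv_res <- NULL
  if (!is.null(bundle$survival)) {
    if (is.null(axis_genes)) axis_genes <- head(grs_top$gene_id, 5)
    axis_genes <- intersect(axis_genes, rownames(bundle$expression$counts))
    surv_res <- stage("survival_axis", stratify_activity(
      bundle$expression, axis_genes, bundle$survival, min_prop = min_prop
    ))
    emit(tidy(surv_res), "activity_groups.tsv")
    emit(glance(surv_res), "survival_summary.tsv")
  } else {
    inform("no survival table supplied; survival stage skipped")
  }

  if (!is.null(out_dir)) {
    yaml::write_yaml(params, file.path(out_dir, "params.yaml"))
  }
  structure(
    list(
      umrs = umrs, dmrs = dmrs, dmr_summary = dmr_summary,
      dmr_context = dmr_context, de = de, qc = qc$qc, homeobox = homeobox,
      delta_umr = delta_tbl, correlations = correlations, overlap = overlap,
      snv = snv, spectrum = spectrum, grs = grs, grs_top = grs_top,
      survival = surv_res, params = params
    ),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  UMRs: %d   DMRs: %d (%.1f%% hypo)\n",
              nrow(x$umrs), nrow(x$dmrs),
              x$dmr_summary$hypo_fraction %||% NA))
  cat(sprintf("  DE: %d up / %d down   aHBG: %d / uHBG: %d\n",
              sum(x$de$status == "up"), sum(x$de$status == "down"),
              sum(x$homeobox$class == "aHBG"), sum(x$homeobox$class == "uHBG")))
  cat(sprintf("  aHBG x hyper overlap: %.1f%% (p = %.3g)\n",
              x$overlap$fraction_of_a, x$overlap$p_value))
  cat(sprintf("  GRS genes scored: %d (top: %s)\n",
              nrow(x$grs$scores), paste(head(x$grs_top$gene_id, 3), collapse = ", ")))
  if (!is.null(x$survival)) {
    cat(sprintf("  survival: cutoff %.3f, log-rank p = %.4g\n",
                x$survival$cutoff, x$survival$logrank$p_value))
  }
  invisible(x)
}

# TSV with a provenance header comment (tool version, seed, parameter hash)
write_output_table <- function(tbl, path, params) {
  ver <- as.character(utils::packageVersion("epidrivers"))
  hdr <- sprintf("# epidrivers %s seed=%s params=%s", ver, params$seed,
                 rlang::hash(params))
  writeLines(hdr, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
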