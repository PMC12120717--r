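#' Filter lowly expressed genes
#'
#' Keeps genes whose count is strictly greater than `min_count` in at
#' least `ceiling(min_frac * n_samples)` samples (the canonical filter is
#' a count > 10 in at least 5% of samples).
#'
#' @param expr an [expression_set()].
#' @param min_count count threshold, strict (default 10).
#' @param min_frac minimum fraction of samples (default 0.05).
#' @return The filtered [expression_set()].
#' @export
filter_low_expression <- function(expr, min_count = 10, min_frac = 0.05) {
  stopifnot(inherits(expr, "expression_set"))
  need <- max(1L, ceiling(min_frac * ncol(expr$counts)))
  keep <- rowSums(expr$counts > min_count) >= need
  expression_set(expr$counts[keep, , drop = FALSE], expr$samples)
}

#' Sample quality control by network connectivity
#'
#' The connectivity of a sample is the sum of its Pearson correlations
#' (on `log2(count + 1)` profiles) with every other sample. Connectivity
#' values are standardized across samples and samples with
#' `Z < z_thresh` are flagged as outliers. When the connectivity
#' standard deviation is zero (e.g. identical samples) all Z scores are
#' defined as 0 and nothing is removed. With `iterative = TRUE` the
#' removal is repeated until no sample falls below the threshold.
#'
#' @param expr an [expression_set()] with at least 3 samples.
#' @param z_thresh standardized-connectivity threshold (default -2).
#' @param iterative repeat until stable (default `FALSE`, single pass).
#' @return A list with `qc` (tibble `sample_id, connectivity, z,
#'   retained`), `retained` and `removed` sample id vectors, and
#'   `expression` (the subsetted [expression_set()]).
#' @export
sample_qc_connectivity <- function(expr, z_thresh = -2, iterative = FALSE) {
  stopifnot(inherits(expr, "expression_set"))
  if (ncol(expr$counts) < 3) abort("connectivity QC requires at least 3 samples")
  current <- expr$samples$sample_id
  removed <- character()
  qc <- NULL
  repeat {
    lc <- log2(expr$counts[, current, drop = FALSE] + 1)
    cm <- suppressWarnings(cor(lc, method = "pearson"))
    cm[is.na(cm)] <- 0
    conn <- rowSums(cm) - diag(cm)
    s <- sd(conn)
    z <- if (is.na(s) || s == 0) rep(0, length(conn)) else (conn - mean(conn)) / s
    qc <- tibble(
      sample_id = current, connectivity = unname(conn), z = unname(z),
      retained = z >= z_thresh
    )
    drop_now <- qc$sample_id[!qc$retained]
    if (!length(drop_now) || !iterative) {
      removed <- c(removed, drop_now)
      current <- setdiff(current, drop_now)
      break
    }
    removed <- c(removed, drop_now)
    current <- setdiff(current, drop_now)
    if (length(current) < 3) break
  }
  keep_meta <- expr$samples[expr$samples$sample_id %in% current, ]
  list(
    qc = qc,
    retained = current,
    removed = removed,
    expression = expression_set(expr$counts[, current, drop = FALSE], keep_meta)
  )
}

#' Median-of-ratios library size factors
#'
#' DESeq-style size factors: per sample, the median ratio of counts to
#' the per-gene geometric mean, computed over genes expressed in every
#' sample.
#'
#' @param counts genes x samples count matrix.
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  log_counts <- log(counts)
  log_gm <- rowMeans(log_counts)
  usable <- is.finite(log_gm)
  if (!any(usable)) abort("no gene is expressed in every sample; cannot normalize")
  sf <- apply(counts[usable, , drop = FALSE], 2, function(x) {
    exp(median(log(x) - log_gm[usable]))
  })
  sf
}

# tumor/normal column indices matched through pair_id
matched_pairs <- function(samples) {
  tum <- samples[samples$condition == "tumor", ]
  nrm <- samples[samples$condition == "normal", ]
  pairs <- intersect(tum$pair_id, nrm$pair_id)
  if (length(pairs) < nrow(tum) || length(pairs) < nrow(nrm)) {
    abort("every tumor sample must have a matched normal via pair_id")
  }
  list(
    pair_id = pairs,
    tumor = tum$sample_id[match(pairs, tum$pair_id)],
    normal = nrm$sample_id[match(pairs, nrm$pair_id)]
  )
}

#' Paired differential expression
#'
#' Counts are normalized with median-of-ratios size factors. Per gene,
#' the log2 fold change is the mean over tumor/normal pairs of
#' `log2((tumor + pseudocount) / (normal + pseudocount))` on normalized
#' counts; the p-value comes from a paired two-sided Wilcoxon
#' signed-rank test on normalized log2 counts, adjusted with
#' Benjamini-Hochberg. Status is `up` iff `lfc >= lfc_cut` and
#' `q <= fdr`, `down` iff `lfc <= -lfc_cut` and `q <= fdr`, otherwise
#' `unchanged`.
#'
#' @param expr an [expression_set()] with a paired tumor/normal design
#'   (at least 3 pairs).
#' @param lfc_cut absolute log2 fold-change threshold (default 1).
#' @param fdr FDR threshold (default 0.05).
#' @param pseudocount added before the log ratio (default 0.5).
#' @return tibble `gene_id, lfc, p_value, q_value, status`.
#' @export
differential_expression <- function(expr, lfc_cut = 1, fdr = 0.05,
                                    pseudocount = 0.5) {
  stopifnot(inherits(expr, "expression_set"))
  mp <- matched_pairs(expr$samples)
  if (length(mp$pair_id) < 3) abort("paired differential expression needs >= 3 pairs")
  sf <- size_factors(expr$counts)
  norm <- sweep(expr$counts, 2, sf, "/")
  tum <- norm[, mp$tumor, drop = FALSE]
  nrm <- norm[, mp$normal, drop = FALSE]
  lfc <- rowMeans(log2((tum + pseudocount) / (nrm + pseudocount)))
  log_diffs <- log2(tum + pseudocount) - log2(nrm + pseudocount)
  p <- apply(log_diffs, 1, paired_wilcoxon_p)
  q <- p.adjust(p, method = "BH")
  tibble(
    gene_id = rownames(expr$counts),
    lfc = unname(lfc),
    p_value = unname(p),
    q_value = unname(q),
    status = de_status(lfc, q, lfc_cut, fdr)
  )
}

de_status <- function(lfc, q, lfc_cut = 1, fdr = 0.05) {
  ifelse(lfc >= lfc_cut & q <= fdr, "up",
         ifelse(lfc <= -lfc_cut & q <= fdr, "down", "unchanged"))
}

#' Read an externally produced differential-expression table
#'
#' Accepts tables produced by other DE engines (e.g. a DESeq2 results
#' export) with columns `gene_id`, `lfc` and `q_value`; status is
#' (re)assigned from the standard thresholds so the downstream pipeline
#' behaves identically.
#'
#' @param path TSV file with header `gene_id`, `lfc`, `q_value`.
#' @param lfc_cut,fdr status thresholds (defaults 1 and 0.05).
#' @return tibble `gene_id, lfc, q_value, status`.
#' @export
read_de_table <- function(path, lfc_cut = 1, fdr = 0.05) {
  tab <- read_tsv_strict(path)
  need <- c("gene_id", "lfc", "q_value")
  if (!all(need %in% names(tab))) {
    abort("DE table must have columns gene_id, lfc, q_value")
  }
  mutate(tab, status = de_status(.data$lfc, .data$q_value, lfc_cut, fdr))
}

#' Classify homeobox genes as activated or unactivated
#'
#' Activated homeobox genes (aHBGs) are homeobox genes significantly
#' upregulated in tumors (`status == "up"`); unactivated homeobox genes
#' (uHBGs) are those downregulated or unchanged. Homeobox ids absent
#' from the DE table are ignored with a warning.
#'
#' @param de tibble with `gene_id` and `status` columns (from
#'   [differential_expression()] or [read_de_table()]).
#' @param homeobox_ids character vector of homeobox gene ids.
#' @return tibble `gene_id, class` with `class` in `{"aHBG", "uHBG"}`.
#' @export
classify_homeobox <- function(de, homeobox_ids) {
  if (!length(homeobox_ids)) abort("empty homeobox gene list")
  unknown <- setdiff(homeobox_ids, de$gene_id)
  if (length(unknown)) {
    warn(sprintf("%d homeobox id(s) absent from the DE table were ignored", length(unknown)))
  }
  de %>%
    filter(.data$gene_id %in% homeobox_ids) %>%
    transmute(
      gene_id = .data$gene_id,
      class = ifelse(.data$status == "up", "aHBG", "uHBG")
    ) %>%
    arrange(.data$gene_id)
}
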