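#' Mask low-coverage CpG observations
#'
#' Per sample, sites covered by fewer than `min_cov` reads are masked
#' (treated as missing, i.e. counts set to zero); sites left with no
#' observation in any sample are dropped.
#'
#' @param m a [methylome()].
#' @param min_cov minimum read coverage for a CpG observation to be kept
#'   (default 4).
#' @return A coverage-filtered [methylome()].
#' @export
filter_by_coverage <- function(m, min_cov = 4) {
  stopifnot(inherits(m, "methylome"), min_cov >= 0)
  if (min_cov == 0) return(m)
  mask <- m$total < min_cov
  m$meth[mask] <- 0L
  m$total[mask] <- 0L
  keep <- rowSums(m$total) > 0
  if (!any(keep)) {
    warn("all CpG sites fall below the coverage threshold; returning empty methylome")
  }
  m$sites <- m$sites[keep, , drop = FALSE]
  m$meth <- m$meth[keep, , drop = FALSE]
  m$total <- m$total[keep, , drop = FALSE]
  m
}

# per-site mean beta across the requested samples (NaN -> NA when no data)
site_mean_beta <- function(m, samples = NULL) {
  b <- beta_values(m)
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, m$samples$sample_id)
    if (length(missing_s)) abort(paste0("unknown samples: ", paste(missing_s, collapse = ", ")))
    b <- b[, m$samples$sample_id %in% samples, drop = FALSE]
  }
  mb <- rowMeans(b, na.rm = TRUE)
  mb[is.nan(mb)] <- NA_real_
  mb
}

#' Mean methylation of a genomic interval
#'
#' Each CpG's beta is first averaged across the requested samples, then
#' the per-site means are averaged (unweighted by coverage) over all CpGs
#' falling in the interval.
#'
#' @param m a [methylome()].
#' @param chrom,start,end interval in 0-based half-open coordinates.
#' @param samples character vector of sample ids (default: all).
#' @return A single mean methylation level in `[0, 1]`.
#' @export
region_mean_methylation <- function(m, chrom, start, end, samples = NULL) {
  stopifnot(inherits(m, "methylome"), end > start)
  inside <- m$sites$chrom == chrom & (m$sites$pos - 1L) >= start & (m$sites$pos - 1L) < end
  mb <- site_mean_beta(m, samples)[inside]
  mb <- mb[!is.na(mb)]
  if (!length(mb)) {
    abort(sprintf("no covered CpG in %s:%d-%d for the requested samples", chrom, start, end))
  }
  mean(mb)
}

#' Call under-methylated regions (UMRs)
#'
#' UMRs are maximal runs of consecutive covered CpGs whose mean
#' methylation across the requested samples is at or below
#' `umr_max_meth` (the canonical definition is an average methylation
#' level of <= 10%), containing at least `umr_min_cpgs` CpGs and with no
#' inter-CpG gap larger than `max_gap_bp`. CpGs with no coverage in the
#' requested samples are ignored (they neither extend nor break a run,
#' but do not shrink gap distances).
#'
#' @param m a coverage-filtered [methylome()].
#' @param samples sample ids to average over (default: all).
#' @param umr_max_meth maximum mean beta inside a UMR (default 0.10).
#' @param umr_min_cpgs minimum CpGs per UMR (default 10).
#' @param max_gap_bp maximum distance between consecutive CpGs in a run
#'   (default 1000).
#' @return tibble `chrom, start, end, n_cpgs, mean_meth` (0-based
#'   half-open intervals spanning first to last CpG + 1).
#' @export
call_umrs <- function(m, samples = NULL, umr_max_meth = 0.10,
                      umr_min_cpgs = 10, max_gap_bp = 1000) {
  stopifnot(inherits(m, "methylome"))
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    n_cpgs = integer(), mean_meth = double()
  )
  if (nrow(m$sites) == 0) return(empty)
  mb <- site_mean_beta(m, samples)
  keep <- !is.na(mb)
  sites <- m$sites[keep, , drop = FALSE]
  mb <- mb[keep]
  if (!nrow(sites)) return(empty)
  low <- mb <= umr_max_meth
  new_chrom <- c(TRUE, sites$chrom[-1] != sites$chrom[-nrow(sites)])
  gap_break <- c(FALSE, diff(sites$pos) > max_gap_bp) | new_chrom
  # a new run starts at every low site that is not a low-continuation
  run_start <- low & (gap_break | !c(FALSE, low[-length(low)]))
  run_id <- ifelse(low, cumsum(run_start), NA_integer_)
  if (!any(low)) return(empty)
  runs <- tibble(
    chrom = sites$chrom, pos = sites$pos, beta = mb, run = run_id
  ) %>%
    filter(!is.na(.data$run)) %>%
    group_by(.data$run) %>%
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$pos) - 1L,
      end = max(.data$pos),  # last CpG (1-based) + 1 in half-open 0-based
      n_cpgs = n(),
      mean_meth = mean(.data$beta),
      .groups = "drop"
    ) %>%
    filter(.data$n_cpgs >= umr_min_cpgs) %>%
    arrange(.data$chrom, .data$start) %>%
    select(-"run")
  runs
}

#' Call differentially methylated regions (DMRs)
#'
#' Candidate regions are formed by merging consecutive CpGs whose
#' tumor-minus-normal mean methylation difference shares sign and has
#' absolute value >= `min_diff / 2` (gaps larger than `max_gap_bp`
#' break a candidate). Candidates with at least `min_cpgs` CpGs are
#' tested with a paired two-sided Wilcoxon signed-rank test on
#' per-sample region means; p-values are Benjamini-Hochberg adjusted
#' across candidates, and regions with `q < fdr` and a region-level
#' mean difference of at least `min_diff` in absolute value are emitted.
#'
#' @param m a coverage-filtered [methylome()] whose sample metadata pairs
#'   every tumor sample with a normal sample via `pair_id`.
#' @param min_diff minimum absolute region mean difference (default 0.1).
#' @param min_cpgs minimum CpGs per region (default 10).
#' @param fdr Benjamini-Hochberg threshold (default 0.05).
#' @param max_gap_bp maximum distance between consecutive candidate CpGs
#'   (default 1000).
#' @return tibble `chrom, start, end, n_cpgs, mean_diff, p_value,
#'   q_value, direction` with `direction` `"hyper"` (tumor-higher) or
#'   `"hypo"`.
#' @export
call_dmrs <- function(m, min_diff = 0.1, min_cpgs = 10, fdr = 0.05,
                      max_gap_bp = 1000) {
  stopifnot(inherits(m, "methylome"))
  smp <- m$samples
  pairs <- intersect(
    smp$pair_id[smp$condition == "tumor"],
    smp$pair_id[smp$condition == "normal"]
  )
  if (!length(pairs)) abort("no tumor/normal pairing metadata in methylome samples")
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    n_cpgs = integer(), mean_diff = double(), p_value = double(),
    q_value = double(), direction = character()
  )
  if (nrow(m$sites) == 0) return(empty)

  b <- beta_values(m)
  tum_cols <- match(pairs, ifelse(smp$condition == "tumor", smp$pair_id, NA))
  nrm_cols <- match(pairs, ifelse(smp$condition == "normal", smp$pair_id, NA))
  bt <- b[, tum_cols, drop = FALSE]
  bn <- b[, nrm_cols, drop = FALSE]
  d <- rowMeans(bt, na.rm = TRUE) - rowMeans(bn, na.rm = TRUE)
  d[is.nan(d)] <- NA_real_

  keep <- !is.na(d)
  sites <- m$sites[keep, , drop = FALSE]
  d <- d[keep]
  bt <- bt[keep, , drop = FALSE]
  bn <- bn[keep, , drop = FALSE]
  if (!nrow(sites)) return(empty)

  eligible <- abs(d) >= min_diff / 2
  sgn <- sign(d)
  new_chrom <- c(TRUE, sites$chrom[-1] != sites$chrom[-nrow(sites)])
  brk <- new_chrom | c(FALSE, diff(sites$pos) > max_gap_bp) |
    c(TRUE, sgn[-1] != sgn[-length(sgn)])
  run_start <- eligible & (brk | !c(FALSE, eligible[-length(eligible)]))
  run_id <- ifelse(eligible, cumsum(run_start), NA_integer_)

  cand_ids <- unique(run_id[!is.na(run_id)])
  cands <- purrr::map_dfr(cand_ids, function(rid) {
    idx <- which(!is.na(run_id) & run_id == rid)
    if (length(idx) < min_cpgs) return(NULL)
    # per-pair region means over the candidate's CpGs
    tmeans <- colMeans(bt[idx, , drop = FALSE], na.rm = TRUE)
    nmeans <- colMeans(bn[idx, , drop = FALSE], na.rm = TRUE)
    ok <- is.finite(tmeans) & is.finite(nmeans)
    if (sum(ok) < 3) return(NULL)
    diffs <- tmeans[ok] - nmeans[ok]
    p <- paired_wilcoxon_p(diffs)
    tibble(
      chrom = sites$chrom[idx[1]],
      start = sites$pos[idx[1]] - 1L,
      end = sites$pos[idx[length(idx)]],
      n_cpgs = length(idx),
      mean_diff = mean(diffs),
      p_value = p
    )
  })
  if (is.null(cands) || nrow(cands) == 0) return(empty)
  cands$q_value <- p.adjust(cands$p_value, method = "BH")
  cands %>%
    filter(.data$q_value < fdr, abs(.data$mean_diff) >= min_diff) %>%
    mutate(direction = ifelse(.data$mean_diff > 0, "hyper", "hypo")) %>%
    arrange(.data$chrom, .data$start)
}

# two-sided paired Wilcoxon signed-rank p-value on a vector of
# per-pair differences; zero differences dropped per convention
paired_wilcoxon_p <- function(diffs) {
  diffs <- diffs[abs(diffs) > .Machine$double.eps^0.5]
  if (length(diffs) < 1) return(1)
  suppressWarnings(
    wilcox.test(diffs, mu = 0, alternative = "two.sided", exact = FALSE,
                correct = TRUE)$p.value
  )
}

#' Summarize a DMR set by direction
#'
#' @param dmrs tibble as returned by [call_dmrs()] (only the `direction`
#'   column is used), or any tibble with a `direction` column.
#' @return One-row tibble `n_hyper, n_hypo, hypo_fraction` (percent) and
#'   `fold_ratio` (`n_hypo / n_hyper`); fractions are `NA` for empty
#'   input and the ratio is `NA` when there are no hyper-DMRs.
#' @export
summarize_dmrs <- function(dmrs) {
  n_hyper <- sum(dmrs$direction == "hyper")
  n_hypo <- sum(dmrs$direction == "hypo")
  total <- n_hyper + n_hypo
  tibble(
    n_hyper = n_hyper,
    n_hypo = n_hypo,
    hypo_fraction = if (total > 0) 100 * n_hypo / total else NA_real_,
    fold_ratio = if (n_hyper > 0) n_hypo / n_hyper else NA_real_
  )
}

# strand-aware promoter windows as 0-based half-open intervals
promoter_windows <- function(gene_models, promoter_up = 1500, promoter_down = 500) {
  gene_models %>%
    mutate(
      prom_start = as.integer(pmax(
        0L, ifelse(strand == "+", tss - promoter_up, tss + 1L - promoter_down)
      )),
      prom_end = as.integer(ifelse(
        strand == "+", tss + promoter_down, tss + 1L + promoter_up
      ))
    )
}

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

#' Assign genomic context labels to regions
#'
#' Each region receives exactly one label with precedence
#' promoter > gene body > intergenic. The promoter is the strand-aware
#' window `[tss - promoter_up, tss + promoter_down)`; any 1-bp overlap
#' counts. Ties across genes are broken by distance to the TSS and then
#' lexicographic gene id.
#'
#' @param regions tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param gene_models tibble from [read_gene_models()].
#' @param promoter_up,promoter_down promoter window extent upstream /
#'   downstream of the TSS in bp (defaults 1500 / 500).
#' @return `regions` with added `context` (`promoter`/`gene_body`/
#'   `intergenic`) and `gene_id` (`NA` for intergenic) columns.
#' @export
annotate_context <- function(regions, gene_models, promoter_up = 1500,
                             promoter_down = 500) {
  regions <- as_tibble(regions)
  if (nrow(regions) == 0) {
    return(mutate(regions, context = character(), gene_id = character()))
  }
  gm <- promoter_windows(gene_models, promoter_up, promoter_down)
  gr_reg <- regions_to_granges(regions)
  gr_prom <- regions_to_granges(
    tibble(chrom = gm$chrom, start = gm$prom_start, end = gm$prom_end)
  )
  gr_body <- regions_to_granges(gm)

  pick_gene <- function(hits, reg_idx) {
    # hits: integer gene rows overlapping region reg_idx
    s <- regions$start[reg_idx]; e <- regions$end[reg_idx]
    tss <- gm$tss[hits]
    dist <- ifelse(tss >= s & tss < e, 0L, pmin(abs(tss - s), abs(tss - (e - 1L))))
    ord <- order(dist, gm$gene_id[hits])
    hits[ord[1]]
  }

  ov_prom <- GenomicRanges::findOverlaps(gr_reg, gr_prom)
  ov_body <- GenomicRanges::findOverlaps(gr_reg, gr_body)
  prom_by_reg <- split(S4Vectors::subjectHits(ov_prom), S4Vectors::queryHits(ov_prom))
  body_by_reg <- split(S4Vectors::subjectHits(ov_body), S4Vectors::queryHits(ov_body))

  context <- rep("intergenic", nrow(regions))
  gene_id <- rep(NA_character_, nrow(regions))
  for (i in seq_len(nrow(regions))) {
    key <- as.character(i)
    if (!is.null(prom_by_reg[[key]])) {
      context[i] <- "promoter"
      gene_id[i] <- gm$gene_id[pick_gene(prom_by_reg[[key]], i)]
    } else if (!is.null(body_by_reg[[key]])) {
      context[i] <- "gene_body"
      gene_id[i] <- gm$gene_id[pick_gene(body_by_reg[[key]], i)]
    }
  }
  mutate(regions, context = context, gene_id = gene_id)
}

#' Metagene methylation profile across gene bodies
#'
#' Each gene body is rescaled to `[0, 1)` strand-aware (bin 0 at the
#' TSS); CpGs are assigned to `n_bins` equal bins by relative position.
#' Within each gene the per-bin mean of site methylation (sites first
#' averaged across the requested samples) is computed, then bins are
#' averaged across genes. Bins with no CpG in any gene are `NA`.
#'
#' @param m a [methylome()].
#' @param gene_models tibble from [read_gene_models()].
#' @param samples sample ids to average over (default all).
#' @param n_bins number of bins (default 100).
#' @return tibble `bin` (0-based), `mean_meth`, `n_genes`.
#' @export
gene_body_profile <- function(m, gene_models, samples = NULL, n_bins = 100) {
  stopifnot(inherits(m, "methylome"))
  if (n_bins < 1) abort("n_bins must be >= 1")
  mb <- site_mean_beta(m, samples)
  keep <- !is.na(mb)
  sites <- m$sites[keep, , drop = FALSE]
  mb <- mb[keep]
  per_gene <- purrr::map_dfr(seq_len(nrow(gene_models)), function(i) {
    g <- gene_models[i, ]
    inside <- sites$chrom == g$chrom &
      (sites$pos - 1L) >= g$start & (sites$pos - 1L) < g$end
    if (!any(inside)) return(NULL)
    rel <- ((sites$pos[inside] - 1L) - g$start) / (g$end - g$start)
    if (g$strand == "-") rel <- 1 - rel - 1e-12
    bin <- pmin(floor(rel * n_bins), n_bins - 1L)
    tibble(gene_id = g$gene_id, bin = as.integer(bin), beta = mb[inside]) %>%
      group_by(.data$gene_id, .data$bin) %>%
      summarise(beta = mean(.data$beta), .groups = "drop")
  })
  if (is.null(per_gene) || nrow(per_gene) == 0) {
    abort("no gene contains a covered CpG")
  }
  full <- tibble(bin = 0:(n_bins - 1L))
  per_gene %>%
    group_by(.data$bin) %>%
    summarise(mean_meth = mean(.data$beta), n_genes = n(), .groups = "drop") %>%
    right_join(full, by = "bin") %>%
    arrange(.data$bin) %>%
    mutate(n_genes = ifelse(is.na(.data$n_genes), 0L, .data$n_genes))
}

#' Write called regions as a BED6+ table
#'
#' Columns: chrom, start, end, name, score (`-log10(q)` for DMRs, 0
#' otherwise), strand (`.`), then all remaining region columns.
#'
#' @param regions tibble from [call_umrs()] or [call_dmrs()].
#' @param path output path.
#' @param prefix region-name prefix (default `"region"`).
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, prefix = "region") {
  extra <- setdiff(names(regions), c("chrom", "start", "end"))
  out <- tibble(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = paste0(prefix, "_", seq_len(nrow(regions))),
    score = if ("q_value" %in% names(regions)) {
      round(-log10(pmax(regions$q_value, 1e-300)), 3)
    } else 0,
    strand = "."
  )
  readr::write_tsv(bind_cols(out, regions[extra]), path)
  invisible(path)
}
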