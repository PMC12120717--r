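#' Spearman rank correlation test
#'
#' Rank correlation computed as Pearson correlation of average ranks
#' (midranks for ties). The two-sided p-value uses the t approximation
#' with `n - 2` degrees of freedom for `n > 9` and the exact permutation
#' distribution for `n <= 9`.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return tibble `rho, p_value, n`.
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Spearman correlation requires at least 3 complete observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) abort("constant input vector; correlation undefined")
  rho <- cor(rx, ry)
  p <- if (n <= 9) {
    spearman_perm_p(rx, ry, rho)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    2 * pt(-abs(tt), df = n - 2)
  }
  tibble(rho = rho, p_value = min(p, 1), n = n)
}

# exact two-sided permutation p-value for the rank correlation
spearman_perm_p <- function(rx, ry, rho_obs) {
  perms <- all_permutations(seq_along(ry))
  rhos <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

all_permutations <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_permutations(v[-i]))
  }))
}

#' Per-gene tumor-normal methylation change over a region class
#'
#' For each gene, computes the mean methylation over the chosen region
#' class separately in tumor and normal samples and returns the tumor
#' minus normal difference. Region classes:
#' \describe{
#'   \item{`gene_body`}{the full gene interval.}
#'   \item{`promoter`}{the strand-aware promoter window.}
#'   \item{`gene_body_umr`}{the intersection of the supplied UMRs
#'     (called on normal samples, so the reference region is fixed under
#'     tumor hypermethylation) with the gene body.}
#' }
#' Genes whose region class contains no covered CpG are absent from the
#' result, not zero-filled.
#'
#' @param m a coverage-filtered [methylome()].
#' @param gene_models tibble from [read_gene_models()].
#' @param region_class one of `"gene_body"`, `"promoter"`,
#'   `"gene_body_umr"`.
#' @param umrs tibble from [call_umrs()] (required for
#'   `"gene_body_umr"`; call them on the normal samples).
#' @param promoter_up,promoter_down promoter window (defaults 1500/500).
#' @return tibble `gene_id, meth_tumor, meth_normal, delta_meth`.
#' @export
gene_region_delta <- function(m, gene_models,
                              region_class = c("gene_body", "promoter", "gene_body_umr"),
                              umrs = NULL, promoter_up = 1500, promoter_down = 500) {
  region_class <- match.arg(region_class)
  stopifnot(inherits(m, "methylome"))
  regions <- switch(region_class,
    gene_body = gene_models[c("chrom", "start", "end", "gene_id")],
    promoter = {
      pw <- promoter_windows(gene_models, promoter_up, promoter_down)
      tibble(chrom = pw$chrom, start = pw$prom_start, end = pw$prom_end,
             gene_id = pw$gene_id)
    },
    gene_body_umr = {
      if (is.null(umrs)) abort("region_class 'gene_body_umr' requires `umrs`")
      intersect_regions_with_genes(umrs, gene_models)
    }
  )
  if (nrow(regions) == 0) {
    return(tibble(gene_id = character(), meth_tumor = double(),
                  meth_normal = double(), delta_meth = double()))
  }
  tum <- m$samples$sample_id[m$samples$condition == "tumor"]
  nrm <- m$samples$sample_id[m$samples$condition == "normal"]
  bt <- site_mean_beta(m, tum)
  bn <- site_mean_beta(m, nrm)

  gr_sites <- GenomicRanges::GRanges(
    seqnames = m$sites$chrom,
    ranges = IRanges::IRanges(start = m$sites$pos, width = 1L)
  )
  ov <- GenomicRanges::findOverlaps(gr_sites, regions_to_granges(regions))
  if (length(ov) == 0) {
    return(tibble(gene_id = character(), meth_tumor = double(),
                  meth_normal = double(), delta_meth = double()))
  }
  tibble(
    gene_id = regions$gene_id[S4Vectors::subjectHits(ov)],
    bt = bt[S4Vectors::queryHits(ov)],
    bn = bn[S4Vectors::queryHits(ov)]
  ) %>%
    group_by(.data$gene_id) %>%
    summarise(
      meth_tumor = mean(.data$bt, na.rm = TRUE),
      meth_normal = mean(.data$bn, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    filter(is.finite(.data$meth_tumor), is.finite(.data$meth_normal)) %>%
    mutate(delta_meth = .data$meth_tumor - .data$meth_normal)
}

# intersect a region set with gene bodies; one row per overlap piece
intersect_regions_with_genes <- function(regions, gene_models) {
  gr_r <- regions_to_granges(regions)
  gr_g <- regions_to_granges(gene_models)
  ov <- GenomicRanges::findOverlaps(gr_r, gr_g)
  if (length(ov) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  gene_id = character()))
  }
  pieces <- IRanges::pintersect(gr_r[S4Vectors::queryHits(ov)],
                                gr_g[S4Vectors::subjectHits(ov)])
  tibble(
    chrom = as.character(GenomicRanges::seqnames(pieces)),
    start = GenomicRanges::start(pieces) - 1L,
    end = GenomicRanges::end(pieces),
    gene_id = gene_models$gene_id[S4Vectors::subjectHits(ov)]
  )
}

#' Methylation-change vs expression-change correlation for a gene set
#'
#' @param delta_table tibble with `gene_id`, `delta_meth` and `lfc`
#'   columns (join [gene_region_delta()] with a DE table).
#' @param genes optional character vector restricting the correlation to
#'   a gene set (e.g. the aHBGs); default uses every row.
#' @return tibble `rho, p_value, n` ([spearman_test()] output).
#' @export
methylation_expression_correlation <- function(delta_table, genes = NULL) {
  tbl <- delta_table
  if (!is.null(genes)) tbl <- filter(tbl, .data$gene_id %in% genes)
  tbl <- filter(tbl, is.finite(.data$delta_meth), is.finite(.data$lfc))
  if (nrow(tbl) < 3) abort("need >= 3 genes with both deltas defined")
  spearman_test(tbl$delta_meth, tbl$lfc)
}

#' Hypergeometric set-overlap enrichment
#'
#' Tests whether the overlap of two gene sets drawn from a common
#' universe is larger than expected by chance:
#' \eqn{p = P(X \ge k)} for a hypergeometric draw of `|A|` genes from a
#' universe containing `|B|` successes.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @return tibble `n_a, n_b, n_overlap, n_universe, fraction_of_a`
#'   (percentage of A overlapping B) and `p_value`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe))) {
    abort("both sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  tibble(
    n_a = length(set_a),
    n_b = length(set_b),
    n_overlap = k,
    n_universe = length(universe),
    fraction_of_a = if (length(set_a) > 0) 100 * k / length(set_a) else NA_real_,
    p_value = phyper(k - 1, length(set_b),
                     length(universe) - length(set_b), length(set_a),
                     lower.tail = FALSE)
  )
}

#' SNV density per region
#'
#' Counts single-nucleotide variants whose (1-based) position falls in
#' each 0-based half-open region and reports variants per kilobase.
#'
#' @param variants tibble from [read_variants()] (non-SNVs are ignored).
#' @param regions tibble with `chrom`, `start`, `end` and any id columns
#'   (carried through).
#' @return `regions` with added `n_snvs` and `snv_per_kb` columns.
#' @export
snv_density <- function(variants, regions) {
  regions <- as_tibble(regions)
  if (any(regions$end <= regions$start)) abort("zero- or negative-length region")
  snvs <- filter(variants, .data$is_snv)
  counts <- integer(nrow(regions))
  if (nrow(snvs) > 0 && nrow(regions) > 0) {
    gr_v <- GenomicRanges::GRanges(
      seqnames = snvs$chrom, ranges = IRanges::IRanges(start = snvs$pos, width = 1L)
    )
    ov <- GenomicRanges::findOverlaps(gr_v, regions_to_granges(regions))
    tab <- table(S4Vectors::subjectHits(ov))
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  mutate(regions,
         n_snvs = counts,
         snv_per_kb = counts / ((.data$end - .data$start) / 1000))
}

#' Pyrimidine-centered substitution spectrum
#'
#' Single-nucleotide variants are strand-collapsed so the reference base
#' is a pyrimidine (a G>A variant becomes C>T with reverse-complemented
#' trinucleotide context), yielding the six canonical substitution
#' classes. A variant is flagged as CpG-context when the collapsed
#' context carries a G immediately 3' of the mutated base. Indels are
#' excluded and counted separately.
#'
#' @param variants tibble from [read_variants()].
#' @return tibble `class, cpg, n, fraction` covering the observed
#'   class/context combinations, with attribute `n_excluded` giving the
#'   number of excluded non-SNV records.
#' @export
substitution_spectrum <- function(variants) {
  snvs <- filter(variants, .data$is_snv)
  n_excluded <- nrow(variants) - nrow(snvs)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp <- function(s) {
    vapply(strsplit(s, ""), function(b) paste(rev(unname(comp[b])), collapse = ""), "")
  }
  flip <- snvs$ref %in% c("A", "G")
  ref2 <- ifelse(flip, unname(comp[snvs$ref]), snvs$ref)
  alt2 <- ifelse(flip, unname(comp[snvs$alt]), snvs$alt)
  ctx2 <- snvs$context
  ctx2[flip] <- revcomp(ctx2[flip])
  out <- tibble(
    class = paste0(ref2, ">", alt2),
    cpg = substr(ctx2, 3, 3) == "G"
  ) %>%
    count(.data$class, .data$cpg, name = "n") %>%
    mutate(fraction = .data$n / sum(.data$n))
  attr(out, "n_excluded") <- n_excluded
  out
}
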