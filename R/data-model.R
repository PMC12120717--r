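#' Construct a methylome object
#'
#' A `methylome` holds per-CpG methylated/total read counts for a set of
#' samples, together with sample metadata (tumor/normal condition and
#' tumor-normal pair identifiers). CpG positions are 1-based single-base
#' coordinates; all derived intervals (UMRs, DMRs, promoters, gene bodies)
#' use BED-style 0-based half-open coordinates, so a CpG at position `p`
#' lies inside interval `[s, e)` iff `s <= p - 1 < e`.
#'
#' The methylation level at a site in a sample is \eqn{\beta =}
#' methylated/total, defined only where total > 0; `total == 0` encodes a
#' missing (masked) observation and is excluded from all means.
#'
#' @param sites tibble with columns `chrom`, `pos` (1-based CpG position),
#'   sorted by (chrom, pos), no duplicates.
#' @param meth,total integer matrices, sites x samples, `meth <= total`.
#' @param samples tibble with columns `sample_id`, `condition`
#'   (`"tumor"`/`"normal"`) and `pair_id`; row order matches matrix columns.
#' @return An object of class `methylome`.
#' @export
methylome <- function(sites, meth, total, samples) {
  sites <- as_tibble(sites)
  samples <- as_tibble(samples)
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  stopifnot(all(c("sample_id", "condition", "pair_id") %in% names(samples)))
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  if (nrow(meth) != nrow(sites) || nrow(total) != nrow(sites) ||
      ncol(meth) != nrow(samples) || ncol(total) != nrow(samples)) {
    abort("dimensions of `meth`/`total` must be n_sites x n_samples")
  }
  colnames(meth) <- colnames(total) <- samples$sample_id
  if (anyDuplicated(sites[c("chrom", "pos")])) {
    abort("duplicate (chrom, pos) CpG sites are not allowed")
  }
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    sites <- sites[ord, ]
    meth <- meth[ord, , drop = FALSE]
    total <- total[ord, , drop = FALSE]
  }
  if (any(sites$pos < 1)) abort("CpG positions must be >= 1 (1-based)")
  if (any(meth < 0) || any(total < 0)) abort("counts must be non-negative")
  bad <- which(meth > total)
  if (length(bad)) {
    abort(sprintf(
      "methylated count exceeds total count at %d site/sample cell(s); first at site row %d",
      length(bad), ((bad[1] - 1) %% nrow(meth)) + 1
    ))
  }
  if (!all(samples$condition %in% c("tumor", "normal"))) {
    abort("sample condition must be 'tumor' or 'normal'")
  }
  structure(
    list(sites = sites, meth = meth, total = total, samples = samples),
    class = "methylome"
  )
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf(
    "<methylome> %d CpG sites x %d samples (%d tumor / %d normal)\n",
    nrow(x$sites), nrow(x$samples),
    sum(x$samples$condition == "tumor"), sum(x$samples$condition == "normal")
  ))
  invisible(x)
}

#' @export
dim.methylome <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Per-site, per-sample methylation levels
#'
#' @param m a [methylome()].
#' @return Numeric matrix of beta values (methylated/total), `NA` where
#'   total is zero.
#' @export
beta_values <- function(m) {
  stopifnot(inherits(m, "methylome"))
  b <- m$meth / m$total
  b[m$total == 0] <- NA_real_
  b
}

#' @describeIn methylome long-format tibble (one row per site x sample).
#' @param x,... method arguments.
#' @exportS3Method tibble::as_tibble
as_tibble.methylome <- function(x, ...) {
  b <- beta_values(x)
  tibble(
    chrom = rep(x$sites$chrom, times = ncol(b)),
    pos = rep(x$sites$pos, times = ncol(b)),
    sample_id = rep(x$samples$sample_id, each = nrow(b)),
    meth = as.vector(x$meth),
    total = as.vector(x$total),
    beta = as.vector(b)
  )
}

#' Read a methylome table
#'
#' The expected format is a tab-separated table with header columns
#' `chrom`, `pos`, then one `<sample>_meth` / `<sample>_total` column pair
#' per sample (a merged CpG-report-like layout). Gzipped files are read
#' transparently.
#'
#' @param path file path.
#' @param sample_meta tibble with `sample_id`, `condition`, `pair_id`
#'   describing every sample present in the file.
#' @return A [methylome()].
#' @export
read_methylome <- function(path, sample_meta) {
  sample_meta <- as_tibble(sample_meta)
  tab <- read_tsv_strict(path)
  if (!all(c("chrom", "pos") %in% names(tab))) {
    abort("methylome table must have 'chrom' and 'pos' columns")
  }
  want_meth <- paste0(sample_meta$sample_id, "_meth")
  want_total <- paste0(sample_meta$sample_id, "_total")
  missing_cols <- setdiff(c(want_meth, want_total), names(tab))
  if (length(missing_cols)) {
    abort(paste0("missing sample columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tab) > 0 && !is.numeric(tab$pos)) {
    bad <- suppressWarnings(which(is.na(as.numeric(tab$pos))))[1]
    abort(sprintf("malformed 'pos' value at data line %d", if (is.na(bad)) 1L else bad))
  }
  tab$pos <- as.numeric(tab$pos)
  if (anyNA(tab$pos) || any(tab$pos != floor(tab$pos))) {
    bad <- which(is.na(tab$pos) | tab$pos != floor(tab$pos))[1]
    abort(sprintf("malformed 'pos' value at data line %d", bad))
  }
  meth <- as.matrix(tab[want_meth])
  total <- as.matrix(tab[want_total])
  if (anyNA(meth) || anyNA(total)) {
    bad <- which(apply(is.na(meth) | is.na(total), 1, any))[1]
    abort(sprintf("malformed count at data line %d", bad))
  }
  if (anyDuplicated(tab[c("chrom", "pos")])) {
    abort("duplicate (chrom, pos) rows in methylome file")
  }
  methylome(
    sites = tibble(chrom = as.character(tab$chrom), pos = as.integer(tab$pos)),
    meth = meth, total = total, samples = sample_meta
  )
}

#' Write a methylome table
#'
#' @param m a [methylome()].
#' @param path output path (`.gz` suffix gzips).
#' @return `path`, invisibly.
#' @export
write_methylome <- function(m, path) {
  stopifnot(inherits(m, "methylome"))
  out <- bind_cols(
    m$sites,
    as_tibble(m$meth, .name_repair = ~ paste0(m$samples$sample_id, "_meth")),
    as_tibble(m$total, .name_repair = ~ paste0(m$samples$sample_id, "_total"))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read gene models from a BED6-like table
#'
#' Columns: `chrom`, `start` (0-based), `end` (exclusive), `gene_id`,
#' `score` (ignored), `strand` (`+`/`-`). The strand-aware transcription
#' start site (TSS, 0-based position) is `start` for `+` genes and
#' `end - 1` for `-` genes.
#'
#' @param path file path (TSV with header).
#' @return tibble `chrom, start, end, gene_id, score, strand, tss`.
#' @export
read_gene_models <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("chrom", "start", "end", "gene_id", "score", "strand")
  if (!all(need %in% names(tab))) {
    abort(paste0("gene model table must have columns: ", paste(need, collapse = ", ")))
  }
  validate_gene_models(tab)
}

validate_gene_models <- function(tab) {
  tab <- as_tibble(tab)
  if (!all(tab$strand %in% c("+", "-"))) {
    abort("unknown strand symbol in gene models (must be '+' or '-')")
  }
  if (any(tab$start < 0)) abort("gene model start must be >= 0")
  if (any(tab$end <= tab$start)) {
    abort(sprintf("gene '%s' has end <= start", tab$gene_id[which(tab$end <= tab$start)[1]]))
  }
  if (anyDuplicated(tab$gene_id)) abort("duplicate gene_id in gene models")
  tab %>%
    mutate(
      start = as.integer(start), end = as.integer(end),
      tss = as.integer(ifelse(strand == "+", start, end - 1L))
    )
}

#' Write gene models as BED6
#' @param genes tibble as returned by [read_gene_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  readr::write_tsv(genes[c("chrom", "start", "end", "gene_id", "score", "strand")], path)
  invisible(path)
}

#' Read a survival table
#'
#' Columns `sample_id`, `time` (months, > 0) and `event`
#' (1 = death, 0 = censored).
#'
#' @param path file path.
#' @return validated tibble.
#' @export
read_survival <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(tab))) {
    abort("survival table must have columns sample_id, time, event")
  }
  validate_survival(tab)
}

validate_survival <- function(tab) {
  tab <- as_tibble(tab)
  if (anyDuplicated(tab$sample_id)) abort("duplicate sample_id in survival table")
  if (any(!is.finite(tab$time)) || any(tab$time <= 0)) {
    abort("survival time must be a positive finite number")
  }
  if (!all(tab$event %in% c(0, 1))) abort("event must be 0 (censored) or 1 (death)")
  mutate(tab, event = as.integer(event))
}

#' Read a protein-interaction edge list
#'
#' Columns `gene_a`, `gene_b`, `combined_score` (integer confidence,
#' 0-1000). Self-edges are dropped on load; scores outside `[0, 1000]`
#' are an error.
#'
#' @param path file path.
#' @return tibble of edges.
#' @export
read_edges <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("gene_a", "gene_b", "combined_score")
  if (!all(need %in% names(tab))) {
    abort("edge list must have columns gene_a, gene_b, combined_score")
  }
  validate_edges(tab)
}

validate_edges <- function(tab) {
  tab <- as_tibble(tab)
  if (any(tab$combined_score < 0 | tab$combined_score > 1000)) {
    abort("combined_score must lie in [0, 1000]")
  }
  filter(tab, gene_a != gene_b)
}

#' Read a minimal variant table
#'
#' VCF-like TSV with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#' `af` (allele frequency in `[0, 1]`) and `context` (reference
#' trinucleotide centered on the variant). Records where `ref == alt`
#' are rejected; indels (multi-base alleles) are retained but flagged so
#' downstream spectrum code can exclude them.
#'
#' @param path file path.
#' @return tibble of variants with an added logical `is_snv` column.
#' @export
read_variants <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("chrom", "pos", "ref", "alt", "af", "context")
  if (!all(need %in% names(tab))) {
    abort("variant table must have columns chrom, pos, ref, alt, af, context")
  }
  validate_variants(tab)
}

validate_variants <- function(tab) {
  tab <- as_tibble(tab)
  if (any(tab$ref == tab$alt)) abort("variant with ref == alt")
  if (any(tab$af < 0 | tab$af > 1)) abort("allele frequency outside [0, 1]")
  mutate(tab, is_snv = nchar(ref) == 1L & nchar(alt) == 1L)
}

#' Read an expression count matrix
#'
#' TSV with a `gene_id` column followed by one column per sample of
#' non-negative integer counts.
#'
#' @param path file path.
#' @param sample_meta tibble `sample_id`, `condition`, `pair_id`.
#' @return An `expression_set`.
#' @export
read_expression <- function(path, sample_meta) {
  tab <- read_tsv_strict(path)
  if (!"gene_id" %in% names(tab)) abort("expression table must have a gene_id column")
  sample_meta <- as_tibble(sample_meta)
  missing_cols <- setdiff(sample_meta$sample_id, names(tab))
  if (length(missing_cols)) {
    abort(paste0("missing sample columns: ", paste(missing_cols, collapse = ", ")))
  }
  counts <- as.matrix(tab[sample_meta$sample_id])
  rownames(counts) <- tab$gene_id
  expression_set(counts, sample_meta)
}

#' Construct an expression set
#'
#' @param counts genes x samples matrix of non-negative counts with gene
#'   ids as rownames.
#' @param samples tibble `sample_id`, `condition`, `pair_id` matching the
#'   matrix columns.
#' @return An object of class `expression_set`.
#' @export
expression_set <- function(counts, samples) {
  counts <- as.matrix(counts)
  samples <- as_tibble(samples)
  stopifnot(all(c("sample_id", "condition", "pair_id") %in% names(samples)))
  if (ncol(counts) != nrow(samples)) abort("one metadata row per count column required")
  if (is.null(rownames(counts))) abort("counts must carry gene ids as rownames")
  if (any(counts < 0)) abort("counts must be non-negative")
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, samples = samples), class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf(
    "<expression_set> %d genes x %d samples (%d tumor / %d normal)\n",
    nrow(x$counts), ncol(x$counts),
    sum(x$samples$condition == "tumor"), sum(x$samples$condition == "normal")
  ))
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$counts)

#' Write an expression count matrix
#' @param expr an [expression_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  out <- bind_cols(tibble(gene_id = rownames(expr$counts)), as_tibble(expr$counts))
  readr::write_tsv(out, path)
  invisible(path)
}

# strict TSV reader: tab-delimited, header row, gzip transparent
read_tsv_strict <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(sprintf("parse error in '%s' at line %d: %s",
                  path, probs$row[1] + 1L, probs$expected[1]))
  }
  tab
}
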