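#' Network connectivity (first-order degree) per gene
#'
#' Degree = number of distinct interaction partners over edges with
#' `combined_score >= min_score` (the STRING high-confidence convention
#' is a combined score of at least 700). Duplicate edges are
#' deduplicated, self-edges ignored, and genes absent from the edge list
#' get degree 0.
#'
#' @param edges tibble from [read_edges()].
#' @param genes character vector of gene ids to report.
#' @param min_score combined-score cutoff, inclusive (default 700).
#' @return tibble `gene_id, connectivity`.
#' @export
network_connectivity <- function(edges, genes, min_score = 700) {
  kept <- edges %>%
    filter(.data$combined_score >= min_score, .data$gene_a != .data$gene_b)
  und <- tibble(
    a = pmin(kept$gene_a, kept$gene_b),
    b = pmax(kept$gene_a, kept$gene_b)
  ) %>% distinct()
  deg <- c(table(c(und$a, und$b)))
  tibble(
    gene_id = genes,
    connectivity = as.integer(ifelse(genes %in% names(deg), deg[genes], 0L))
  )
}

#' Per-gene minor allele frequency
#'
#' Aggregates variant allele frequencies per gene as the mean AF over
#' the SNVs falling inside the gene interval; genes without variants get
#' 0.
#'
#' @param variants tibble from [read_variants()].
#' @param gene_models tibble from [read_gene_models()].
#' @return tibble `gene_id, maf`.
#' @export
gene_maf <- function(variants, gene_models) {
  snvs <- filter(variants, .data$is_snv)
  out <- tibble(gene_id = gene_models$gene_id, maf = 0)
  if (nrow(snvs) == 0) return(out)
  gr_v <- GenomicRanges::GRanges(
    seqnames = snvs$chrom, ranges = IRanges::IRanges(start = snvs$pos, width = 1L)
  )
  ov <- GenomicRanges::findOverlaps(gr_v, regions_to_granges(gene_models))
  if (length(ov) == 0) return(out)
  agg <- tibble(
    gene_id = gene_models$gene_id[S4Vectors::subjectHits(ov)],
    af = snvs$af[S4Vectors::queryHits(ov)]
  ) %>%
    group_by(.data$gene_id) %>%
    summarise(maf = mean(.data$af), .groups = "drop")
  out$maf[match(agg$gene_id, out$gene_id)] <- agg$maf
  out
}

#' Assemble the Gene Risk Score feature matrix
#'
#' Joins the four per-gene features — log2 fold change, absolute
#' differential methylation, minor allele frequency and network
#' connectivity — with the missense Z constraint score. Genes with any
#' missing feature are dropped with a warning.
#'
#' @param de tibble with `gene_id`, `lfc`.
#' @param delta tibble with `gene_id`, `delta_meth` (signed; the
#'   absolute value becomes the feature).
#' @param maf tibble with `gene_id`, `maf`.
#' @param connectivity tibble with `gene_id`, `connectivity`.
#' @param missense_z tibble with `gene_id`, `missense_z`.
#' @return tibble `gene_id, lfc, abs_dm, maf, connectivity, missense_z`.
#' @export
assemble_grs_features <- function(de, delta, maf, connectivity, missense_z) {
  feats <- de %>%
    select("gene_id", "lfc") %>%
    inner_join(transmute(delta, gene_id = .data$gene_id,
                         abs_dm = abs(.data$delta_meth)), by = "gene_id") %>%
    left_join(select(maf, "gene_id", "maf"), by = "gene_id") %>%
    left_join(select(connectivity, "gene_id", "connectivity"), by = "gene_id") %>%
    inner_join(select(missense_z, "gene_id", "missense_z"), by = "gene_id")
  complete <- complete.cases(feats)
  if (any(!complete)) {
    warn(sprintf("%d gene(s) with missing features dropped from the GRS matrix",
                 sum(!complete)))
  }
  feats[complete, ]
}

grs_feature_columns <- function(features) {
  setdiff(names(features), c("gene_id", "missense_z"))
}

#' Constraint-derived feature weights
#'
#' The weight of each feature column is its Spearman correlation with
#' the gene-level missense Z constraint score, so features that track
#' constraint contribute positively to the risk score. A constant
#' feature column receives weight 0 with a warning.
#'
#' @param features tibble from [assemble_grs_features()] (any numeric
#'   columns besides `gene_id`/`missense_z` are treated as features).
#' @return Named numeric vector of weights, one per feature column.
#' @export
compute_weights <- function(features) {
  if (nrow(features) < 3) abort("weight computation requires >= 3 genes")
  cols <- grs_feature_columns(features)
  z <- features$missense_z
  if (sd(z) == 0) abort("missense_z is constant; weights undefined")
  vapply(setNames(cols, cols), function(cl) {
    x <- features[[cl]]
    if (sd(x) == 0) {
      warn(sprintf("feature '%s' is constant; weight set to 0", cl))
      return(0)
    }
    cor(rank(x, ties.method = "average"), rank(z, ties.method = "average"))
  }, numeric(1))
}

#' Compute the Gene Risk Score
#'
#' The score of gene *i* is the weighted sum over features
#' \eqn{GRS_i = \sum_j \rho_j X'_{ij}}, where the weights are the
#' Spearman correlations of each feature with the missense Z score
#' ([compute_weights()]) and, by default, each feature column is
#' standardized to zero mean and unit variance before the sum (raw
#' features mix incommensurate scales such as allele frequencies and
#' network degrees).
#'
#' @param features tibble from [assemble_grs_features()].
#' @param weights optional named weight vector; computed from
#'   `features` when `NULL`.
#' @param standardize z-score feature columns first (default `TRUE`).
#' @param z_min missense Z threshold for the constraint flag
#'   (default 3.09, the usual intolerance cutoff).
#' @return An object of class `grs_fit` with elements `scores` (tibble
#'   `gene_id, grs, rank, constrained`), `weights`, `standardize`.
#' @export
compute_grs <- function(features, weights = NULL, standardize = TRUE,
                        z_min = 3.09) {
  cols <- grs_feature_columns(features)
  if (is.null(weights)) weights <- compute_weights(features)
  if (length(weights) != length(cols)) {
    abort(sprintf("got %d weights for %d feature columns",
                  length(weights), length(cols)))
  }
  if (!is.null(names(weights)) && !setequal(names(weights), cols)) {
    abort("weight names do not match feature columns")
  }
  if (!is.null(names(weights))) weights <- weights[cols]
  x <- as.matrix(features[cols])
  if (standardize) {
    x <- scale(x)
    x[, attr(x, "scaled:scale") == 0] <- 0  # constant column -> no contribution
  }
  grs <- as.vector(x %*% weights)
  ord <- order(-grs, features$gene_id)
  rank_vec <- integer(length(grs))
  rank_vec[ord] <- seq_along(ord)
  scores <- tibble(
    gene_id = features$gene_id,
    grs = grs,
    rank = rank_vec,
    constrained = flag_constrained(features, z_min = z_min)
  )
  structure(
    list(scores = scores, weights = weights, standardize = standardize),
    class = "grs_fit"
  )
}

#' @export
print.grs_fit <- function(x, ...) {
  cat(sprintf("<grs_fit> %d genes, %d features (standardize = %s)\n",
              nrow(x$scores), length(x$weights), x$standardize))
  cat("weights:\n")
  print(round(x$weights, 4))
  cat("top genes:\n")
  print(head(arrange(x$scores, .data$rank), 5))
  invisible(x)
}

#' Top-ranked genes from a GRS fit
#'
#' Genes sorted by descending score; ties are broken by lexicographic
#' gene id so the selection is deterministic.
#'
#' @param result a `grs_fit` (or its `scores` tibble).
#' @param k number of genes to return (default 15).
#' @return tibble of the `k` highest-scoring rows in rank order.
#' @export
rank_and_select <- function(result, k = 15) {
  if (k < 1) abort("k must be >= 1")
  scores <- if (inherits(result, "grs_fit")) result$scores else as_tibble(result)
  if (k > nrow(scores)) {
    warn(sprintf("k = %d exceeds the %d scored genes; returning all", k, nrow(scores)))
    k <- nrow(scores)
  }
  scores %>% arrange(.data$rank) %>% head(k)
}

#' Flag constraint-intolerant genes
#'
#' @param features tibble with a `missense_z` column.
#' @param z_min inclusive threshold (default 3.09).
#' @return Logical vector, `TRUE` where `missense_z >= z_min`.
#' @export
flag_constrained <- function(features, z_min = 3.09) {
  features$missense_z >= z_min
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a GRS fit into its per-gene score table
#' @param x a `grs_fit`.
#' @param ... unused.
#' @return tibble `gene_id, grs, rank, constrained`.
#' @exportS3Method generics::tidy
tidy.grs_fit <- function(x, ...) {
  arrange(x$scores, .data$rank)
}

#' One-row summary of a GRS fit
#' @param x a `grs_fit`.
#' @param ... unused.
#' @return One-row tibble with gene/feature counts and one `weight_*`
#'   column per feature.
#' @exportS3Method generics::glance
glance.grs_fit <- function(x, ...) {
  w <- as.list(x$weights)
  names(w) <- paste0("weight_", names(w))
  bind_cols(
    tibble(n_genes = nrow(x$scores), n_features = length(x$weights),
           standardize = x$standardize, n_constrained = sum(x$scores$constrained)),
    as_tibble(w)
  )
}
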