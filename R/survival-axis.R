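#' PLAGE pathway activity score
#'
#' Pathway-level activity from the leading singular vector: the
#' `log2(count + 1)` expression of the gene set is z-scored per gene and
#' the per-sample activity is the right singular vector of the largest
#' singular value of the genes x samples matrix. The singular-vector
#' sign is arbitrary, so it is fixed such that the activity correlates
#' non-negatively with the mean z-scored expression of the set — high
#' activity means high axis expression.
#'
#' @param expr an [expression_set()] (or a numeric genes x samples
#'   matrix already on log scale, taken as-is).
#' @param gene_set character vector of gene ids, all present in `expr`
#'   with non-zero variance.
#' @return tibble `sample_id, activity`.
#' @export
plage_score <- function(expr, gene_set) {
  if (!length(gene_set)) abort("empty gene set")
  if (inherits(expr, "expression_set")) {
    mat <- log2(expr$counts + 1)
    sample_ids <- expr$samples$sample_id
  } else {
    mat <- as.matrix(expr)
    sample_ids <- colnames(mat) %||% paste0("S", seq_len(ncol(mat)))
  }
  if (ncol(mat) < 2) abort("PLAGE requires at least 2 samples")
  missing_g <- setdiff(gene_set, rownames(mat))
  if (length(missing_g)) {
    abort(paste0("gene set members absent from expression: ",
                 paste(missing_g, collapse = ", ")))
  }
  sub <- mat[gene_set, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance gene(s) in set: ",
                 paste(gene_set[sds == 0], collapse = ", ")))
  }
  z <- (sub - rowMeans(sub)) / sds
  sv <- svd(z)
  activity <- sv$v[, 1]
  ref <- colMeans(z)
  if (sum(activity * ref) < 0) activity <- -activity
  tibble(sample_id = sample_ids, activity = activity)
}

# two-group log-rank O/E/Var decomposition; groups is a logical vector
# (TRUE = group of interest) aligned with time/event
logrank_oe <- function(time, event, in_group) {
  event_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in event_times) {
    at_risk <- time >= t
    nt <- sum(at_risk)
    n1 <- sum(at_risk & in_group)
    dt <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in_group)
    O <- O + d1
    E <- E + dt * n1 / nt
    if (nt > 1) V <- V + dt * (n1 / nt) * (1 - n1 / nt) * (nt - dt) / (nt - 1)
  }
  list(O = O, E = E, V = V)
}

#' Two-group log-rank test
#'
#' At each distinct event time, observed events in one group are
#' compared with their hypergeometric expectation given the risk sets;
#' the statistic is \eqn{(O - E)^2 / Var} referred to a chi-square
#' distribution with 1 degree of freedom.
#'
#' @param survival tibble `sample_id, time, event`.
#' @param groups vector (character/factor/logical) with exactly two
#'   non-empty levels, aligned with `survival` rows.
#' @return tibble `chi2, p_value` (and `z`, the signed standardized
#'   statistic for the first group level).
#' @export
logrank_test <- function(survival, groups) {
  groups <- as.factor(as.vector(groups))
  if (nlevels(groups) != 2 || any(table(groups) == 0)) {
    abort("log-rank test requires exactly 2 non-empty groups")
  }
  if (length(groups) != nrow(survival)) {
    abort("`groups` must align with the survival table rows")
  }
  oe <- logrank_oe(survival$time, survival$event, groups == levels(groups)[1])
  if (oe$V <= 0) {
    return(tibble(chi2 = 0, p_value = 1, z = 0))
  }
  z <- (oe$O - oe$E) / sqrt(oe$V)
  chi2 <- z^2
  tibble(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE), z = z)
}

#' Maximally selected log-rank cutpoint
#'
#' Evaluates every candidate cutpoint (midpoints between consecutive
#' sorted unique scores) that leaves at least a proportion `min_prop`
#' of samples on each side, and returns the one maximizing the absolute
#' standardized log-rank statistic between the resulting low
#' (`score <= cut`) and high (`score > cut`) groups. Ties go to the
#' smaller cutpoint.
#'
#' @param scores tibble `sample_id, activity` (e.g. from
#'   [plage_score()]) or a numeric vector aligned with `survival`.
#' @param survival tibble `sample_id, time, event` (>= 10 samples, >= 1
#'   event).
#' @param min_prop minimum proportion of samples per side (default 0.1).
#' @return One-row tibble `cutoff, statistic` (`statistic` = maximal
#'   absolute standardized log-rank statistic).
#' @export
optimal_cutoff <- function(scores, survival, min_prop = 0.1) {
  x <- align_scores(scores, survival)
  n <- nrow(survival)
  if (n < 10) abort("cutpoint selection requires >= 10 samples")
  if (sum(survival$event) < 1) abort("cutpoint selection requires >= 1 event")
  u <- sort(unique(x))
  if (length(u) < 2) abort("all scores are equal; no cutpoint exists")
  cands <- (u[-1] + u[-length(u)]) / 2
  valid <- vapply(cands, function(cut) {
    nl <- sum(x <= cut)
    nl / n >= min_prop && (n - nl) / n >= min_prop
  }, logical(1))
  cands <- cands[valid]
  if (!length(cands)) abort("no candidate cutpoint satisfies min_prop")
  stat <- vapply(cands, function(cut) {
    oe <- logrank_oe(survival$time, survival$event, x > cut)
    if (oe$V <= 0) 0 else abs(oe$O - oe$E) / sqrt(oe$V)
  }, numeric(1))
  best <- which(stat >= max(stat) - 1e-12)[1]  # ties -> smaller cutpoint
  tibble(cutoff = cands[best], statistic = stat[best])
}

align_scores <- function(scores, survival) {
  if (is.data.frame(scores)) {
    idx <- match(survival$sample_id, scores$sample_id)
    if (anyNA(idx)) abort("scores missing for some survival samples")
    scores$activity[idx]
  } else {
    if (length(scores) != nrow(survival)) {
      abort("score vector must align with survival rows")
    }
    as.numeric(scores)
  }
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate via [survival::survfit()]; samples censored at
#' an event time are counted at risk for that time.
#'
#' @param survival tibble `sample_id, time, event` (>= 1 sample).
#' @return tibble `time, n_risk, n_event, n_censor, survival`.
#' @export
km_estimate <- function(survival) {
  if (nrow(survival) < 1) abort("empty survival table")
  fit <- survival::survfit(
    survival::Surv(survival$time, survival$event) ~ 1,
    conf.type = "none"
  )
  tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
}

#' Survival stratification by pathway activity
#'
#' End-to-end axis analysis: PLAGE activity per sample, maximally
#' selected log-rank cutpoint, high/low grouping (`high` iff
#' `activity > cutoff`) and the log-rank comparison of the two groups.
#' The reported p-value is the plain log-rank p at the selected cutoff
#' (no selection correction); treat it as descriptive.
#'
#' @param expr an [expression_set()] covering the survival samples.
#' @param gene_set axis gene ids (e.g. the regulatory-axis members).
#' @param survival tibble `sample_id, time, event`.
#' @param min_prop minimum group proportion for the cutpoint search
#'   (default 0.1).
#' @return An object of class `activity_result`: list with `activity`
#'   (tibble `sample_id, activity, group, time, event`), `cutoff`,
#'   `cutpoint_statistic`, `logrank` (tibble `chi2, p_value, z`).
#' @export
stratify_activity <- function(expr, gene_set, survival, min_prop = 0.1) {
  scores <- plage_score(expr, gene_set)
  cut <- optimal_cutoff(scores, survival, min_prop = min_prop)
  act <- scores[match(survival$sample_id, scores$sample_id), ]
  groups <- ifelse(act$activity > cut$cutoff, "high", "low")
  lr <- logrank_test(survival, groups)
  structure(
    list(
      activity = tibble(
        sample_id = survival$sample_id,
        activity = act$activity,
        group = groups,
        time = survival$time,
        event = survival$event
      ),
      cutoff = cut$cutoff,
      cutpoint_statistic = cut$statistic,
      logrank = lr
    ),
    class = "activity_result"
  )
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf(
    "<activity_result> %d samples (high: %d, low: %d), cutoff = %.4f\n",
    nrow(x$activity), sum(x$activity$group == "high"),
    sum(x$activity$group == "low"), x$cutoff
  ))
  cat(sprintf("log-rank chi2 = %.3f, p = %.4g\n", x$logrank$chi2, x$logrank$p_value))
  invisible(x)
}

#' Tidy an activity stratification into its per-sample table
#' @param x an `activity_result`.
#' @param ... unused.
#' @return tibble `sample_id, activity, group, time, event`.
#' @exportS3Method generics::tidy
tidy.activity_result <- function(x, ...) x$activity

#' One-row summary of an activity stratification
#' @param x an `activity_result`.
#' @param ... unused.
#' @return One-row tibble with group sizes, cutoff and the log-rank
#'   statistic and p-value.
#' @exportS3Method generics::glance
glance.activity_result <- function(x, ...) {
  tibble(
    n = nrow(x$activity),
    n_high = sum(x$activity$group == "high"),
    n_low = sum(x$activity$group == "low"),
    cutoff = x$cutoff,
    logrank_chi2 = x$logrank$chi2,
    logrank_p = x$logrank$p_value
  )
}
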