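test_that("singleton and duplicated-gene PLAGE reduce to the z-scored gene", {
  set.seed(71)
  mat <- matrix(rnorm(36, 8, 2), nrow = 3,
                dimnames = list(c("g1", "g2", "g3"), sprintf("S%02d", 1:12)))
  act1 <- plage_score(mat, "g1")
  z <- (mat["g1", ] - mean(mat["g1", ])) / sd(mat["g1", ])
  # rank-1 case: activity is the unit-normalized z-scored gene
  expect_equal(act1$activity, unname(z / sqrt(sum(z^2))), tolerance = 1e-12)

  mat2 <- rbind(mat, g1b = mat["g1", ])
  act_dup <- plage_score(mat2, c("g1", "g1b"))
  expect_equal(act_dup$activity, act1$activity, tolerance = 1e-12)
})

test_that("PLAGE matches an independent eigendecomposition oracle", {
  set.seed(72)
  mat <- matrix(rnorm(60, 10, 3), nrow = 5,
                dimnames = list(paste0("g", 1:5), sprintf("S%02d", 1:12)))
  act <- plage_score(mat, paste0("g", 1:5))
  z <- t(scale(t(mat)))
  ev <- eigen(crossprod(z), symmetric = TRUE)  # t(Z) Z v = d^2 v
  v1 <- ev$vectors[, 1]
  agreement <- abs(sum(act$activity * v1))  # up to sign
  expect_equal(agreement, 1, tolerance = 1e-10)
  # sign convention: non-negative correlation with mean z-expression
  expect_gte(sum(act$activity * colMeans(z)), 0)
})

test_that("PLAGE is invariant to per-gene affine rescaling", {
  set.seed(73)
  counts <- matrix(rnbinom(50, mu = 100, size = 5), nrow = 5,
                   dimnames = list(paste0("g", 1:5), paste0("S", 1:10)))
  lmat <- log2(counts + 1)
  act <- plage_score(lmat, paste0("g", 1:5))
  rescaled <- lmat * c(2, 5, 0.5, 1, 10) + c(1, -3, 0, 7, 2)
  act2 <- plage_score(rescaled, paste0("g", 1:5))
  expect_equal(act$activity, act2$activity, tolerance = 1e-10)
})

test_that("PLAGE errors name zero-variance genes and reject empty sets", {
  mat <- matrix(c(1, 1, 1, 2, 3, 4), nrow = 2, byrow = TRUE,
                dimnames = list(c("flat", "ok"), paste0("S", 1:3)))
  expect_error(plage_score(mat, c("flat", "ok")), "flat")
  expect_error(plage_score(mat, character()), "empty")
  expect_error(plage_score(mat[, 1, drop = FALSE], "ok"), "2 samples")
})

test_that("log-rank matches the hand-computed O/E/Var table", {
  # group A events at t = 1, 2; group B events at t = 3, 4; no censoring
  surv <- tibble::tibble(sample_id = paste0("S", 1:4),
                         time = c(1, 2, 3, 4), event = 1L)
  res <- logrank_test(surv, c("A", "A", "B", "B"))
  # O_A = 2, E_A = 1/2 + 1/3 = 5/6, Var = 1/4 + 2/9 = 17/36
  expect_equal(res$chi2, (2 - 5 / 6)^2 / (17 / 36), tolerance = 1e-12)
  expect_equal(res$chi2, 49 / 17, tolerance = 1e-12)

  expect_error(logrank_test(surv, c("A", "A", "A", "A")), "2 non-empty")
})

test_that("log-rank agrees with survival::survdiff and is label-symmetric", {
  set.seed(74)
  for (i in 1:5) {
    n <- 40
    surv <- tibble::tibble(
      sample_id = sprintf("S%02d", 1:n),
      time = rexp(n, 0.05),
      event = rbinom(n, 1, 0.7)
    )
    g <- sample(c("x", "y"), n, TRUE, prob = c(0.5, 0.5))
    if (length(unique(g)) < 2) next
    mine <- logrank_test(surv, g)
    ref <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)
    expect_equal(mine$chi2, unname(ref$chisq), tolerance = 1e-8)
    flipped <- logrank_test(surv, ifelse(g == "x", "y", "x"))
    expect_equal(mine$chi2, flipped$chi2, tolerance = 1e-12)
  }
})

test_that("identical groups give a near-zero log-rank statistic", {
  surv <- tibble::tibble(
    sample_id = paste0("S", 1:20),
    time = rep(c(2, 5, 9, 14, 20, 26, 33, 41, 50, 60), 2),
    event = rep(c(1, 1, 1, 0, 1, 1, 0, 1, 1, 0), 2)
  )
  res <- logrank_test(surv, rep(c("a", "b"), each = 10))
  expect_lt(res$chi2, 1e-20)
  expect_gt(res$p_value, 0.999)
})

test_that("Kaplan-Meier estimates match closed forms", {
  s3 <- tibble::tibble(sample_id = paste0("S", 1:3), time = c(1, 2, 3), event = 1L)
  km <- km_estimate(s3)
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)

  cens <- tibble::tibble(sample_id = paste0("S", 1:4), time = 1:4, event = 0L)
  expect_true(all(km_estimate(cens)$survival == 1))

  tie <- tibble::tibble(sample_id = paste0("S", 1:4),
                        time = c(1, 1, 2, 3), event = c(1L, 1L, 0L, 0L))
  km_tie <- km_estimate(tie)
  expect_equal(km_tie$survival[km_tie$time == 1], 0.5)

  expect_error(km_estimate(tie[0, ]), "empty")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(75)
  times <- sort(sample(1:100, 30, replace = TRUE))
  surv <- tibble::tibble(sample_id = sprintf("S%02d", 1:30),
                         time = times, event = 1L)
  km <- km_estimate(surv)
  for (i in seq_len(nrow(km))) {
    expect_equal(km$survival[i], mean(times > km$time[i]), tolerance = 1e-12)
  }
})

test_that("optimal cutoff separates a perfectly split cohort", {
  surv <- tibble::tibble(
    sample_id = paste0("S", 1:10),
    time = c(1, 2, 3, 2, 1, 50, 55, 60, 58, 52),
    event = c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L)
  )
  scores <- c(10, 10, 10, 10, 10, 1, 1, 1, 1, 1)
  res <- optimal_cutoff(scores, surv, min_prop = 0.1)
  expect_gt(res$cutoff, 1)
  expect_lt(res$cutoff, 10)

  expect_error(optimal_cutoff(rep(3, 10), surv), "all scores")
  expect_error(optimal_cutoff(scores, surv, min_prop = 0.6), "min_prop")
})

test_that("cutpoint equals an exhaustive survdiff-based search oracle", {
  set.seed(76)
  n <- 20
  surv <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:n),
    time = rexp(n, 0.04),
    event = rbinom(n, 1, 0.8)
  )
  x <- rnorm(n)
  res <- optimal_cutoff(x, surv, min_prop = 0.1)

  u <- sort(unique(x))
  cands <- (u[-1] + u[-length(u)]) / 2
  stats <- vapply(cands, function(cut) {
    nl <- sum(x <= cut)
    if (nl / n < 0.1 || (n - nl) / n < 0.1) return(-Inf)
    g <- factor(ifelse(x > cut, "high", "low"))
    sqrt(survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)$chisq)
  }, 0)
  expect_equal(res$cutoff, cands[which.max(stats)], tolerance = 1e-12)
  expect_equal(res$statistic, max(stats), tolerance = 1e-8)
})

test_that("stratify_activity separates a planted prognostic activity", {
  sim <- simulate_activity_survival(n_samples = 120, seed = 77)
  res <- stratify_activity(sim$expression, sim$axis_genes, sim$survival)
  expect_s3_class(res, "activity_result")
  expect_true(all(c("high", "low") %in% res$activity$group))
  # recovered activity tracks the planted one
  act <- dplyr::inner_join(tidy(res), sim$activity, by = "sample_id")
  expect_gt(cor(act$activity.x, act$activity.y, method = "spearman"), 0.8)
  # high-activity group fares worse
  km_high <- km_estimate(dplyr::filter(res$activity, group == "high"))
  km_low <- km_estimate(dplyr::filter(res$activity, group == "low"))
  median_surv <- function(km) km$time[which(km$survival <= 0.5)[1]]
  expect_lt(median_surv(km_high), median_surv(km_low))
  expect_lt(res$logrank$p_value, 0.05)
  g <- glance(res)
  expect_equal(g$n, 120L)
})
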