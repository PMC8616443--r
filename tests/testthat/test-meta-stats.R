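test_that("Pearson r with t-based p matches the closed form", {
  res <- pearson_with_p(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(res$r, 0.8)
  expect_equal(res$df, 3)
  # p from an independent t-CDF evaluation at t = 0.8 sqrt(3 / 0.36)
  t_expected <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(res$t, t_expected)
  expect_equal(res$p, 2 * pt(-abs(t_expected), 3))
  # perfect linearity
  x <- 1:5
  res2 <- pearson_with_p(x, 2 * x + 1)
  expect_equal(res2$r, 1)
  expect_equal(res2$p, 0)
  expect_error(pearson_with_p(1:2, 1:2), "3")
  expect_error(pearson_with_p(1:5, rep(1, 5)), "variance")
})

test_that("Pearson p agrees with cor.test across random inputs", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    x <- runif(n); y <- 0.5 * x + rnorm(n, sd = 0.3)
    got <- pearson_with_p(x, y)
    ref <- cor.test(x, y)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Pearson r is invariant under affine rescaling", {
  set.seed(8)
  x <- runif(12); y <- runif(12)
  r0 <- pearson_with_p(x, y)$r
  expect_equal(pearson_with_p(3 * x + 7, y)$r, r0)
  expect_equal(pearson_with_p(x, -2 * y + 1)$r, -r0)
})

test_that("perpendicular fit recovers exact lines and the TLS closed form", {
  x <- c(0, 1, 2, 3, 4)
  f <- perpendicular_fit(x, x, nboot = 0)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$perp_rss, 0)
  # closed-form oracle on a random cloud
  set.seed(44)
  xs <- rnorm(20); ys <- 1.7 * xs + rnorm(20, sd = 0.6)
  fit <- perpendicular_fit(xs, ys, nboot = 0)
  sxx <- sum((xs - mean(xs))^2); syy <- sum((ys - mean(ys))^2)
  sxy <- sum((xs - mean(xs)) * (ys - mean(ys)))
  b <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  expect_equal(fit$slope, b)
  expect_equal(fit$intercept, mean(ys) - b * mean(xs))
  # axis-swap reciprocity
  swapped <- perpendicular_fit(ys, xs, nboot = 0)
  expect_equal(swapped$slope, 1 / fit$slope, tolerance = 1e-10)
  # vertical best-fit line reported explicitly
  v <- perpendicular_fit(c(2, 2, 2, 2), c(0, 1, 2, 5), nboot = 0)
  expect_true(v$vertical)
  expect_equal(v$x0, 2)
  expect_error(perpendicular_fit(rep(1, 4), rep(1, 4)), "coincident")
})

test_that("perpendicular bootstrap bands are seeded and sensible", {
  set.seed(9)
  xs <- runif(25); ys <- xs + rnorm(25, sd = 0.2)
  f1 <- perpendicular_fit(xs, ys, seed = 5, nboot = 300)
  f2 <- perpendicular_fit(xs, ys, seed = 5, nboot = 300)
  expect_equal(f1$conf_halfwidth, f2$conf_halfwidth)
  # prediction bands dominate confidence bands
  expect_true(all(f1$pred_halfwidth >= f1$conf_halfwidth - 1e-9))
  expect_true(all(f1$conf_halfwidth > 0))
})

test_that("the n-1 chi-squared equals the hand-built 2x2 Pearson form", {
  # identical rates and sizes -> statistic 0, p = 1
  expect_equal(chi2_nminus1(c(30, 50), c(30, 50))$p, 1)
  got <- chi2_nminus1(c(28, 40), c(180, 433))
  # contingency-table oracle: Pearson chi2 scaled by (N-1)/N
  ref <- suppressWarnings(
    chisq.test(matrix(c(28, 12, 180, 253), nrow = 2, byrow = TRUE),
               correct = FALSE)$statistic)
  expect_equal(got$statistic, unname(ref) * 472 / 473, tolerance = 1e-12)
  expect_equal(got$p, pchisq(got$statistic, 1, lower.tail = FALSE))
  # symmetry
  expect_equal(chi2_nminus1(c(28, 40), c(180, 433))$p,
               chi2_nminus1(c(180, 433), c(28, 40))$p)
  # zero margin -> p = 1 by convention
  expect_equal(chi2_nminus1(c(0, 10), c(0, 20))$p, 1)
})

test_that("pairwise match fractions count p > 0.05 and within-10pt pairs", {
  same <- data.frame(measured_responders = c(5, 10),
                     measured_total = c(10, 20),
                     predicted_numerator = c(50, 100),
                     predicted_denominator = c(100, 200))
  expect_equal(pairwise_match_summary(same, "p_gt_0.05"), 1)
  expect_equal(pairwise_match_summary(same, "within_10pct"), 1)
  # exactly 10 points apart counts as within (inclusive boundary)
  edge <- data.frame(measured_responders = 6, measured_total = 10,
                     predicted_numerator = 50,
                     predicted_denominator = 100)
  expect_equal(pairwise_match_summary(edge, "within_10pct"), 1)
  # enumeration oracle over a random set
  prs <- rand_pairs(17, n = 30)
  ps <- vapply(seq_len(nrow(prs)), function(i) {
    chi2_nminus1(c(prs$measured_responders[i], prs$measured_total[i]),
                 c(prs$predicted_numerator[i],
                   prs$predicted_denominator[i]))$p
  }, numeric(1))
  expect_equal(pairwise_match_summary(prs, "p_gt_0.05"), mean(ps > 0.05))
  d <- abs(prs$measured_responders / prs$measured_total -
             prs$predicted_numerator / prs$predicted_denominator)
  expect_equal(pairwise_match_summary(prs, "within_10pct"),
               mean(d <= 0.10))
})

test_that("ROC endpoints: perfect separation and constant scores", {
  prs <- data.frame(measured_responders = c(8, 9, 1, 2),
                    measured_total = 10,
                    predicted_numerator = c(90, 80, 20, 10),
                    predicted_denominator = 100)
  expect_equal(roc_for_threshold(prs, 70)$auc, 1)
  prs$predicted_numerator <- 50
  expect_equal(roc_for_threshold(prs, 70)$auc, 0.5)
  # single-class labelling is degenerate
  prs$measured_responders <- c(8, 9, 9, 8)
  deg <- roc_for_threshold(prs, 70)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$auc))
})

test_that("trapezoidal AUC equals the tie-corrected rank-sum value", {
  for (seed in 1:20) {
    prs <- rand_pairs(seed + 100, n = sample(8:30, 1))
    r <- roc_for_threshold(prs, 50)
    if (r$degenerate) next
    labels <- prs$measured_responders / prs$measured_total >= 0.5
    scores <- prs$predicted_numerator / prs$predicted_denominator
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC complements under score negation on tie-free data", {
  set.seed(55)
  prs <- rand_pairs(200, n = 20)
  scores <- prs$predicted_numerator / prs$predicted_denominator
  if (anyDuplicated(scores) == 0) {
    labels <- prs$measured_responders / prs$measured_total >= 0.5
    a1 <- oracle_auc(scores, labels)
    a2 <- oracle_auc(-scores, labels)
    expect_equal(a1 + a2, 1)
  }
  r <- roc_for_threshold(prs, 50)
  expect_gte(r$auc, 0); expect_lte(r$auc, 1)
})

test_that("the AUC sweep is the per-threshold composition", {
  prs <- rand_pairs(300, n = 25)
  sweep <- auc_sweep(prs, thresholds = seq(30, 80, 10))
  for (i in seq_len(nrow(sweep))) {
    expect_equal(sweep$auc[i],
                 roc_for_threshold(prs, sweep$threshold[i])$auc)
  }
  # perfectly self-predicting pairs give AUC 1 wherever non-degenerate
  perf <- data.frame(measured_responders = c(2, 4, 6, 8),
                     measured_total = 10,
                     predicted_numerator = c(20, 40, 60, 80),
                     predicted_denominator = 100)
  sw <- auc_sweep(perf)
  expect_true(all(sw$auc[!sw$degenerate] == 1))
})

test_that("group comparisons delegate to rank and mean tests correctly", {
  a <- c(1, 2, 3, 4, 5); b <- c(1, 2, 3, 4, 5)
  expect_equal(group_location_test(a, b, "rank"), 1)
  set.seed(4)
  g1 <- rnorm(20); g2 <- g1 + 50
  expect_lt(group_location_test(g1, g2, "rank"), 0.001)
  expect_lt(group_location_test(g1, g2, "mean"), 0.001)
  # rank-sum oracle with ties
  for (seed in 1:10) {
    set.seed(seed)
    x <- sample(1:6, 12, replace = TRUE)
    y <- sample(2:8, 15, replace = TRUE)
    expect_equal(group_location_test(x, y, "rank"), oracle_rank_p(x, y),
                 tolerance = 1e-10)
  }
})

test_that("per-position binder frequencies match a per-subject recount", {
  inst <- rand_instance(402, max_subjects = 10, max_antigens = 1)
  ag <- inst$vacc$antigens[1]
  gm <- as.matrix(as.data.frame(inst$pop)[, c("A1", "A2", "B1", "B2",
                                              "C1", "C2")])
  for (n in c(1, 2, 4)) {
    got <- per_position_binder_frequency(inst$pop, ag, inst$tbl, n)
    L <- nchar(ag)
    expect_length(got, L - 8)
    want <- numeric(L - 8)
    for (s in 0:(L - 9)) {
      pep <- substr(ag, s + 1, s + 9)
      cnt <- 0
      for (i in seq_len(nrow(gm))) {
        if (count_binding_alleles(pep, gm[i, ], inst$tbl) >= n) {
          cnt <- cnt + 1
        }
      }
      want[s + 1] <- cnt / nrow(gm)
    }
    expect_equal(unname(got), want)
  }
  # elementwise monotone in the HLA cutoff
  f1 <- per_position_binder_frequency(inst$pop, ag, inst$tbl, 1)
  f4 <- per_position_binder_frequency(inst$pop, ag, inst$tbl, 4)
  expect_true(all(f4 <= f1))
})

test_that("mean epitope count equals the per-position column sum", {
  inst <- rand_instance(403, max_subjects = 8, max_antigens = 1)
  ag <- inst$vacc$antigens[1]
  for (n in 1:3) {
    m <- mean_epitope_count(inst$pop, ag, inst$tbl, n)
    f <- per_position_binder_frequency(inst$pop, ag, inst$tbl, n)
    expect_equal(m, sum(f))
  }
  # monotone in n; empty table -> 0
  expect_gte(mean_epitope_count(inst$pop, ag, inst$tbl, 1),
             mean_epitope_count(inst$pop, ag, inst$tbl, 2))
  empty <- binding_table(data.frame(peptide = character(0),
                                    allele = character(0),
                                    percentile_rank = numeric(0)))
  expect_equal(mean_epitope_count(inst$pop, ag, empty, 1), 0)
})
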