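# replication_stats: Fisher test, power, dataset correlation, burden

test_that("fisher_allele_test matches closed-form OR and the stats oracle", {
  ft <- fisher_allele_test(12, 88, 4, 196)
  expect_equal(ft$or, (12 * 196) / (88 * 4))
  expect_equal(round(ft$or, 3), 6.682)
  expect_equal(ft$p,
               fisher.test(matrix(c(12, 88, 4, 196), 2, byrow = TRUE))$p.value)
  # symmetric equal-AF table
  ft2 <- fisher_allele_test(10, 90, 10, 90)
  expect_equal(ft2$or, 1)
  expect_equal(ft2$p, 1)
  # both alt columns zero
  ft3 <- fisher_allele_test(0, 100, 0, 100)
  expect_equal(ft3$p, 1)
  expect_true(ft3$undefined)
  # zero cell: continuity-corrected OR, flagged
  ft4 <- fisher_allele_test(5, 95, 0, 100)
  expect_true(ft4$or_corrected)
  expect_equal(ft4$or, (5.5 * 100.5) / (95.5 * 0.5))
  expect_error(fisher_allele_test(-1, 1, 1, 1), "non-negative")
})

test_that("fisher_allele_test equals fisher.test across small tables", {
  set.seed(2)
  for (rep in 1:200) {
    tab <- sample(0:15, 4, replace = TRUE)
    if (tab[1] + tab[2] == 0 || tab[3] + tab[4] == 0) next
    if (tab[1] + tab[3] == 0) next
    mine <- fisher_allele_test(tab[1], tab[2], tab[3], tab[4])$p
    oracle <- fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    expect_equal(mine, oracle, tolerance = 1e-10,
                 info = paste(tab, collapse = ","))
  }
})

test_that("min_phenotype_result selects smallest p with IBD-first ties", {
  res <- data.frame(phenotype = c("IBD", "CD", "UC"),
                    p = c(1e-3, 1e-5, 0.2), or = c(2, 3, 1))
  expect_equal(min_phenotype_result(res)$phenotype, "CD")
  res$p <- rep(0.5, 3)
  expect_equal(min_phenotype_result(res)$phenotype, "IBD")
  expect_equal(min_phenotype_result(res[2, ])$phenotype, "CD")
})

test_that("cc_power is calibrated at the null and monotone in OR", {
  alpha <- 0.05
  set.seed(5)
  p_null <- cc_power(0.04, 1, 500, 500, alpha, n_sims = 2000)
  se <- sqrt(alpha * (1 - alpha) / 2000)
  expect_lte(p_null, alpha + 3 * se)   # Fisher is conservative
  pw <- vapply(c(1.5, 2.5, 4), function(or) {
    set.seed(9)
    cc_power(0.04, or, 500, 500, alpha, n_sims = 1000)
  }, 0)
  expect_true(all(diff(pw) >= 0))
  expect_gt(pw[3], 0.9)
  expect_error(cc_power(0.04, -1, 10, 10, 0.05))
})

test_that("find_or_for_power brackets and refines the required OR", {
  set.seed(1)
  r <- find_or_for_power(0.1, 2000, 2000, alpha = 1e-4, target = 0.8,
                         n_sims = 1000, seed = 3)
  expect_false(r$unreachable)
  # verify: power just below/above the boundary
  set.seed(3)
  expect_gte(cc_power(0.1, r$or_raw + 0.1, 2000, 2000, 1e-4, 2000), 0.75)
  # larger cohort -> smaller required OR
  r_big <- find_or_for_power(0.1, 8000, 8000, alpha = 1e-4, target = 0.8,
                             n_sims = 1000, seed = 3)
  expect_lt(r_big$or_raw, r$or_raw)
  # unreachable target flagged
  r_cap <- find_or_for_power(0.001, 20, 20, alpha = 1e-8, target = 0.9,
                             n_sims = 200, seed = 3, or_max = 10)
  expect_true(r_cap$unreachable)
})

test_that("effective_dataset_count merges correlated datasets", {
  set.seed(4)
  n <- 60
  base <- runif(n)
  # CD ~ IBD strongly correlated; UC independent
  m <- cbind(IBD = base, CD = base + rnorm(n, 0, 0.05), UC = runif(n))
  res <- effective_dataset_count(m)
  expect_equal(res$n_effective, 2)
  expect_equal(res$components[["IBD"]], res$components[["CD"]])
  # three mutually independent -> 3
  m3 <- cbind(A = runif(n), B = runif(n), C = runif(n))
  expect_equal(effective_dataset_count(m3)$n_effective, 3)
  # invariant to dataset ordering
  expect_equal(effective_dataset_count(m[, c(3, 1, 2)])$n_effective, 2)
  # two datasets only, correlated -> 1
  expect_equal(effective_dataset_count(m[, 1:2])$n_effective, 1)
  expect_warning(effective_dataset_count(matrix(runif(4), 2, 2)),
                 "fewer than")
})

test_that("test_budget reproduces the published arithmetic", {
  b <- test_budget(11, 413, 2, 1)
  expect_equal(b$total_tests, 11 * 2 + 413 * 3)
  expect_equal(signif(bonferroni_threshold(b), 3), 3.97e-5)
  expect_equal(bonferroni_threshold(test_budget(1, 0, 1, 0)), 0.05)
  expect_error(test_budget(0, 0, 2, 1), "empty")
})

test_that("count_significant thresholds on min p", {
  res <- data.frame(key = letters[1:4],
                    min_p = c(2.7e-26, 3.7e-4, 0.16, NA))
  out <- count_significant(res, 3.97e-5)
  expect_equal(out$n, 1)
  expect_equal(out$keys, "a")
  expect_equal(count_significant(res, 1)$n, 3)
  expect_equal(count_significant(res[0, ], 0.05)$n, 0)
})

test_that("compare_af_distributions is a rank test", {
  x <- c(1e-4, 2e-4, 5e-4, 1e-3)
  expect_gt(compare_af_distributions(x, x), 0.9)
  set.seed(6)
  a <- runif(50, 0, 1); b <- runif(50, 2, 3)   # disjoint supports
  expect_lt(compare_af_distributions(a, b), 1e-10)
  # invariant to a common monotone transform
  expect_equal(compare_af_distributions(log(a), log(b)),
               compare_af_distributions(a, b))
})

test_that("cmc_burden_test collapses by AF bin and is calibrated", {
  set.seed(10)
  n <- 400
  pcs <- matrix(rnorm(n * 5), n, 5)
  y <- rbinom(n, 1, 0.5)
  # no carriers at all
  g0 <- matrix(0L, n, 3)
  expect_equal(cmc_burden_test(g0, y, pcs, af = c(0.001, 0.001, 0.02))$p, 1)
  # null calibration: carriers independent of status
  g <- cbind(rbinom(n, 1, 0.05), rbinom(n, 1, 0.03), rbinom(n, 1, 0.08))
  af <- c(0.005, 0.002, 0.03)
  ps <- replicate(200, cmc_burden_test(g, sample(y), pcs, af)$p)
  t1 <- mean(ps < 0.05)
  expect_lt(abs(t1 - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 0.02)
  # planted burden: carriers enriched in cases
  risk <- rbinom(n, 1, 0.06)
  y2 <- rbinom(n, 1, plogis(qlogis(0.4) + log(5) * risk))
  res <- cmc_burden_test(cbind(g, risk), y2, pcs, c(af, 0.004))
  expect_lt(res$p, stats::median(ps))
  expect_gte(res$llr, 0)
  expect_equal(res$df, 2)
})

test_that("cmc_burden_test falls back to a penalized fit under separation", {
  set.seed(11)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  g <- matrix(0L, n, 1)
  g[y == 1, 1] <- rbinom(n / 2, 1, 0.9)   # carriers only among cases
  pcs <- matrix(rnorm(n * 5), n, 5)
  res <- cmc_burden_test(g, y, pcs, af = 0.001)
  expect_true(res$separated)
  expect_true(is.finite(res$llr))
  expect_lt(res$p, 0.05)
})
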