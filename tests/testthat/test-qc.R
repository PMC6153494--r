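# qc: genotype/variant filters, sex, kinship, ancestry

test_that("genotype_qc applies GQ, depth and allele-balance rules", {
  th <- qc_thresholds()
  expect_equal(genotype_qc(1, 99, 10, 10, th), "pass")
  # 20:1 het: continuity-corrected chi-square p well below 0.001
  p <- allele_balance_p(20, 1)
  expect_lt(p, 0.001)
  expect_equal(genotype_qc(1, 99, 20, 1, th), "allele_balance")
  expect_equal(genotype_qc(2, 99, 0, 2, th), "depth")
  expect_equal(genotype_qc(1, 10, 10, 10, th), "gq")
  expect_equal(genotype_qc(NA, 99, 10, 10, th), "missing")
  expect_equal(genotype_qc(1, NA, 10, 10, th), "unevaluable")
  expect_equal(
    genotype_qc(1, NA, 10, 10, qc_thresholds(missing_quality = "fail")),
    "missing_quality")
})

test_that("allele_balance_p matches a direct binomial chi-square oracle", {
  for (pair in list(c(10, 10), c(15, 5), c(30, 12), c(8, 1))) {
    oracle <- suppressWarnings(
      stats::prop.test(pair[1], sum(pair), p = 0.5)$p.value)
    expect_equal(allele_balance_p(pair[1], pair[2]), oracle,
                 tolerance = 1e-10)
  }
})

test_that("hwe_chi2 matches expectations", {
  expect_equal(hwe_chi2(25, 50, 25), 1.0)
  # all-homozygote split: chi-square statistic equals n
  n <- 100
  expect_equal(hwe_chi2(50, 0, 50),
               pchisq(n, df = 1, lower.tail = FALSE))
  expect_lt(hwe_chi2(50, 0, 50), 5e-8)
  expect_equal(hwe_chi2(100, 0, 0), 1.0)  # monomorphic
  expect_error(hwe_chi2(0, 0, 0), "zero")
})

test_that("variant_qc enforces tranche, call-rate and HWE bounds", {
  g <- matrix(rep(c(0L, 1L), 10), nrow = 20, ncol = 3)
  vs <- make_vs(g)
  vs$variants$vqsr_tranche <- c(99.5, 99.6, 95)
  vs$variants$is_snp <- c(TRUE, TRUE, FALSE)
  res <- variant_qc(vs)
  expect_true(res$pass[1])                        # SNP at 99.5 passes
  expect_match(res$reasons[2], "tranche")         # SNP at 99.6 fails
  expect_true(res$pass[3])                        # indel at 95 passes
  vs$variants$vqsr_tranche[3] <- 99.3             # indel above 99.0
  expect_match(variant_qc(vs)$reasons[3], "tranche")
  # 10 of 20 genotypes missing -> call rate 0.5 < 0.75
  vs2 <- make_vs(matrix(c(rep(NA_integer_, 10), rep(1L, 10)), ncol = 1))
  expect_match(variant_qc(vs2)$reasons[1], "call_rate")
})

test_that("variant_qc is monotone in thresholds", {
  set.seed(7)
  g <- matrix(sample(c(0:2, NA), 200, TRUE, prob = c(.5, .3, .1, .1)),
              20, 10)
  vs <- make_vs(g)
  vs$variants$vqsr_tranche <- runif(10, 90, 100)
  strict <- variant_qc(vs, qc_thresholds())
  relaxed <- variant_qc(vs, qc_thresholds(min_call_rate = 0.5,
                                          hwe_p_min = 1e-12,
                                          max_tranche_snp = 100))
  expect_true(all(relaxed$pass[strict$pass]))
})

test_that("infer_sex uses two thresholds with an ambiguous band", {
  expect_equal(infer_sex(0.99), "male")
  expect_equal(infer_sex(0.65), "female")
  expect_equal(infer_sex(0.85), "ambiguous")
  expect_error(infer_sex(0.9, n_variants = 10), "too few")
  # expected female hom rate under HWE on a synthetic AF spectrum stays
  # below the female threshold
  af <- runif(500, 0.05, 0.5)
  exp_hom <- mean(af^2 + (1 - af)^2)
  expect_equal(infer_sex(exp_hom), "female")
})

test_that("kinship bins partition the line and match printed cut points", {
  expect_equal(classify_kinship(0.25), "first")
  expect_equal(classify_kinship(0.40), "duplicate")
  expect_equal(classify_kinship(0.01), "unrelated")
  expect_equal(classify_kinship(0.354), "first")    # boundary inclusive down
  expect_equal(classify_kinship(0.177), "first")
  expect_equal(classify_kinship(0.0884), "second")
  expect_equal(classify_kinship(-0.05), "unrelated")
  phis <- seq(-0.5, 0.5, by = 0.001)
  classes <- classify_kinship(phis)
  expect_true(all(classes %in%
                    c("duplicate", "first", "second", "third", "unrelated")))
})

test_that("pedigree_kinship reproduces textbook coefficients", {
  fam <- nuclear_family("K", 2, c("CD", "CD"))
  k <- pedigree_kinship(fam)
  expect_equal(k["K_p1", "K_c1"], 0.25)   # parent-offspring
  expect_equal(k["K_c1", "K_c2"], 0.25)   # full sibs
  # half sibs: shared father, different mothers
  hs <- data.frame(
    id = c("f", "m1", "m2", "a", "b"), family_id = "H",
    father_id = c(NA, NA, NA, "f", "f"),
    mother_id = c(NA, NA, NA, "m1", "m2"),
    sex = c("male", "female", "female", "male", "male"),
    phenotype = "unaffected", sequenced = TRUE)
  expect_equal(pedigree_kinship(hs)["a", "b"], 0.125)
  # first cousins via a three-generation pedigree -> 0.0625, third degree
  tg <- three_gen_family("C")
  kc <- pedigree_kinship(tg)
  expect_equal(kc["C_k11", "C_k21"], 0.0625)
  expect_equal(classify_kinship(0.0625), "third")
})

test_that("pedigree_kinship agrees with gene-drop IBD sharing", {
  # kinship = P(two alleles drawn one from each individual are IBD);
  # estimate by dropping a rare allele and measuring co-carriage:
  # E[cov(dosage)/ (2 af(1-af))] = 2 phi for non-inbred pairs
  fam <- three_gen_family("M")
  set.seed(99)
  dos <- drop_family(fam, 0.5, 40000)
  k <- pedigree_kinship(fam)
  for (pair in list(c("M_s1", "M_k11"), c("M_k11", "M_k12"),
                    c("M_k11", "M_k21"))) {
    emp <- cov(dos[pair[1], ], dos[pair[2], ]) / (2 * 0.5 * 0.5)
    expect_lt(abs(emp - 2 * k[pair[1], pair[2]]), 0.02)
  }
})

test_that("ancestry ellipsoid covers ~90% and uses the chi-square radius", {
  set.seed(31)
  n <- 4000
  pts <- matrix(rnorm(n * 5), n, 5) %*% diag(c(3, 2, 1.5, 1, 0.5))
  model <- fit_ancestry_ellipsoid(pts)
  expect_equal(model$d2_threshold, qchisq(0.90, df = 5))
  cov_frac <- mean(in_ellipsoid(model, pts))
  # binomial CI at n = 4000: 0.90 +/- ~3*0.0047
  expect_lt(abs(cov_frac - 0.90), 0.02)
  expect_true(in_ellipsoid(model, matrix(model$mean, 1)))  # centre
  expect_error(fit_ancestry_ellipsoid(pts[1:4, ]), "more points")
})

test_that("outlier trimming removes gross contaminants before the fit", {
  set.seed(5)
  clean <- matrix(rnorm(1000 * 5), 1000, 5)
  contam <- matrix(rnorm(30 * 5, mean = 12), 30, 5)
  model <- fit_ancestry_ellipsoid(rbind(clean, contam))
  expect_gt(length(model$outliers), 20)
  expect_lt(sum(in_ellipsoid(model, contam)), 3)
})

test_that("rank_proximal_controls orders by Mahalanobis distance", {
  set.seed(8)
  pts <- matrix(rnorm(500 * 5), 500, 5)
  model <- fit_ancestry_ellipsoid(pts)
  cand <- rbind(centre = model$mean,
                far = model$mean + 10)
  cand <- rbind(cand, matrix(rnorm(50 * 5, sd = 2), 50, 5,
                             dimnames = list(sprintf("c%02d", 1:50), NULL)))
  ranked <- rank_proximal_controls(model, cand, k = nrow(cand))
  expect_equal(ranked[1], "centre")
  expect_equal(sort(ranked), sort(rownames(cand)))  # k = n permutation
  expect_warning(rank_proximal_controls(model, cand, k = 1000), "exceeds")
  # mixture: selection enriches the model component
  mix <- rbind(matrix(rnorm(100 * 5), 100, 5,
                      dimnames = list(paste0("in", 1:100), NULL)),
               matrix(rnorm(100 * 5, mean = 8), 100, 5,
                      dimnames = list(paste0("out", 1:100), NULL)))
  sel <- rank_proximal_controls(model, mix, k = 100)
  expect_gt(mean(grepl("^in", sel)), 0.95)
})

test_that("genotype_concordance counts co-observed sites only", {
  expect_equal(genotype_concordance(c(0, 1, 2), c(0, 1, 2)), 1.0)
  expect_equal(genotype_concordance(c(rep(0, 499), 1), c(rep(0, 499), 2)),
               0.998)
  expect_equal(genotype_concordance(c(0, NA, 2), c(NA, 1, 2)), 1.0)
  expect_error(genotype_concordance(c(NA, NA), c(1, NA)), "co-observed")
})

test_that("pca_fit projects held-out samples with training loadings", {
  set.seed(21)
  train <- matrix(rbinom(200 * 30, 2, 0.3), 200, 30)
  fit <- pca_fit(train, n_pcs = 3)
  proj <- fit$project(train[1:10, ])
  expect_equal(unname(proj), unname(fit$scores[1:10, ]), tolerance = 1e-8)
})
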