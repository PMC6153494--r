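# synthetic_data: pedigree/genotype/phenotype simulation, LOD and
# replication tables, determinism

test_that("simulate_pedigree builds valid three-generation structures", {
  fam <- simulate_pedigree("F1", 3, 3)
  expect_s3_class(fam, "family_ped")
  # 2 top founders + 3 married-in spouses
  expect_equal(sum(is.na(fam$father_id)), 5)
  # every non-founder has two in-family parents
  nf <- fam[!is.na(fam$father_id), ]
  expect_true(all(nf$father_id %in% fam$id & nf$mother_id %in% fam$id))
  # kinship oracle: every parent-offspring pair is exactly 0.25
  k <- pedigree_kinship(fam)
  for (i in which(!is.na(fam$father_id)))
    expect_equal(k[fam$id[i], fam$father_id[i]], 0.25)
  expect_error(simulate_pedigree("X", 1), "two generations")
})

test_that("simulated cohorts honour ascertainment and lfam forcing", {
  cfg <- sim_config(seed = 42, n_families = 10, n_lfams = 3,
                    n_sporadic_cases = 12, n_controls = 9, n_variants = 5)
  co <- simulate_cohort(cfg)
  ind <- co$individuals
  expect_equal(sum(ind$role == "sporadic_case"), 12)
  expect_equal(sum(ind$role == "control"), 9)
  for (f in family_ids(co)) {
    n_aff <- length(affected_members(get_family(co, f), "IBD"))
    expect_gte(n_aff, 2)
  }
  expect_true(all(attr(co, "lfam_designated") %in% select_lfams(co, "IBD")))
})

test_that("simulated genotypes recover founder AFs and HWE among founders", {
  cfg <- sim_config(seed = 7, n_families = 30, n_lfams = 2,
                    n_sporadic_cases = 150, n_controls = 150,
                    n_variants = 12,
                    founder_af_range = c(0.05, 0.3))
  co <- simulate_cohort(cfg)
  gt <- simulate_genotypes(co, cfg)
  ind <- co$individuals
  founders <- ind$id[ind$founder]
  n_f <- length(founders)
  hwe_p <- numeric(0)
  for (j in seq_len(nrow(gt$vs$variants))) {
    g <- gt$vs$geno[founders, j]
    af_hat <- mean(g) / 2
    af_true <- gt$truth$founder_af[j]
    se <- sqrt(af_true * (1 - af_true) / (2 * n_f))
    expect_lt(abs(af_hat - af_true), 4 * se)
    hwe_p <- c(hwe_p, hwe_chi2(sum(g == 0), sum(g == 1), sum(g == 2)))
  }
  # founders are unrelated draws: HWE p-values should not pile up small
  expect_gt(mean(hwe_p > 0.05), 0.7)
})

test_that("planted variants are carried by >= 75% of affecteds in targets", {
  planted <- data.frame(key = "9_1000000_A_T", founder_af = 0,
                        n_target_families = 2, carrier_fraction = 0.8,
                        consequence = "frameshift", gene = "PG")
  cfg <- sim_config(seed = 13, n_families = 10, n_lfams = 3,
                    n_sporadic_cases = 5, n_controls = 5, n_variants = 5,
                    planted = planted)
  co <- simulate_cohort(cfg)
  gt <- simulate_genotypes(co, cfg)
  targets <- strsplit(gt$truth$target_families[gt$truth$planted], ",")[[1]]
  expect_length(targets, 2)
  for (f in targets) {
    res <- family_carrier_fraction(gt$vs, "9_1000000_A_T",
                                   get_family(co, f), "IBD")
    expect_true(res$passes_75)
  }
  # non-target families carry nothing (founder AF zero)
  others <- setdiff(family_ids(co), targets)
  ids <- co$individuals$id[co$individuals$family_id %in% others]
  expect_true(all(gt$vs$geno[ids, "9_1000000_A_T"] == 0))
})

test_that("phenotypes are independent of genotype under a null model", {
  cfg <- sim_config(seed = 3)
  fam <- simulate_pedigree("N", 3, 4)
  set.seed(31)
  out <- assign_phenotypes(fam, config = cfg)
  expect_true(all(out$phenotype %in% famrvar:::PHENOTYPE_LEVELS))
  # with a strong familial term affection becomes common
  set.seed(32)
  boosted <- assign_phenotypes(fam, familial = 5, config = cfg)
  base_rate <- mean(pheno_matches(out$phenotype, "IBD"))
  boost_rate <- mean(pheno_matches(boosted$phenotype, "IBD"))
  expect_gt(boost_rate, base_rate)
})

test_that("simulate_lod_table plants a recoverable locus", {
  planted <- data.frame(key = "1_25000000_A_T", founder_af = 0,
                        n_target_families = 2, carrier_fraction = 0.8,
                        consequence = "frameshift", gene = "PG")
  cfg <- sim_config(seed = 19, n_families = 8, n_lfams = 2,
                    n_sporadic_cases = 4, n_controls = 4, n_variants = 4,
                    planted = planted)
  co <- simulate_cohort(cfg)
  gt <- simulate_genotypes(co, cfg)
  lod <- simulate_lod_table(co, gt$vs, "1_25000000_A_T", seed = 19)
  loci <- select_loci(lod$lod_curve)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$peak_lod, 2.074)
  contrib <- contributing_families(lod$per_family_lod, loci[1, ])
  # exactly the carrier-sharing families contribute
  targets <- strsplit(gt$truth$target_families[gt$truth$planted], ",")[[1]]
  expect_setequal(contrib, targets)
  # no planted signal: nothing at threshold
  null_lod <- simulate_lod_table(co, gt$vs, NULL, seed = 19)
  expect_equal(nrow(select_loci(null_lod$lod_curve)), 0)
})

test_that("simulate_replication emits calibrated counts and drops singletons", {
  cohorts <- data.frame(phenotype = "CD", n_cases = 1286L,
                        n_controls = 3035L)
  specs <- data.frame(key = c("k1", "k2", "k3"),
                      control_af = c(0.024, 0.05, 0),
                      true_or = c(3.24, 1, 2))
  repl <- simulate_replication(specs, cohorts, seed = 21)
  expect_false("k3" %in% repl$key)   # zero-AF variant absent
  r1 <- repl[repl$key == "k1", ]
  ft <- fisher_allele_test(r1$case_alt, r1$case_ref, r1$ctrl_alt,
                           r1$ctrl_ref)
  # estimated OR near truth (allele counts are large at these sizes)
  expect_lt(abs(log(ft$or) - log(3.24)), 0.5)
  # null variant: uniform p across seeds (single smoke draw here)
  r2 <- repl[repl$key == "k2", ]
  expect_gt(fisher_allele_test(r2$case_alt, r2$case_ref, r2$ctrl_alt,
                               r2$ctrl_ref)$p, 1e-4)
})

test_that("the generated corpus is identical for a fixed seed", {
  cfg <- sim_config(seed = 77, n_families = 6, n_lfams = 2,
                    n_sporadic_cases = 5, n_controls = 5, n_variants = 6)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cohort$individuals, s2$cohort$individuals)
  expect_identical(s1$vs$geno, s2$vs$geno)
  expect_identical(s1$lod$lod_curve, s2$lod$lod_curve)
  expect_identical(s1$replication, s2$replication)
})
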