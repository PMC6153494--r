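# linkage_support: maps, pruning, trimming, loci, contributing families

test_that("interpolate_cm is linear with flat extrapolation", {
  map <- data.frame(chrom = "1", bp = c(10, 20, 40), cM = c(1, 2, 2.5))
  expect_equal(interpolate_cm(20, map, "1"), 2)
  expect_equal(interpolate_cm(15, map, "1"), 1.5)
  expect_equal(interpolate_cm(5, map, "1"), 1)    # below range: flat
  expect_equal(interpolate_cm(100, map, "1"), 2.5)
  expect_error(interpolate_cm(5, map, "2"), "no map anchors")
})

test_that("ld_prune removes duplicated columns and keeps independent SNPs", {
  set.seed(12)
  base <- matrix(rbinom(200 * 10, 2, 0.3), 200, 10)
  dup <- cbind(base, base[, 5])
  colnames(dup) <- paste0("snp", seq_len(ncol(dup)))
  res <- ld_prune(dup)
  expect_false(all(c("snp5", "snp11") %in% res$kept))
  expect_true(any(c("snp5", "snp11") %in% res$kept))
  # independent SNPs survive
  indep <- matrix(rbinom(500 * 20, 2, 0.4), 500, 20,
                  dimnames = list(NULL, paste0("s", 1:20)))
  res2 <- ld_prune(indep)
  expect_equal(sort(res2$kept), sort(colnames(indep)))
  # postcondition replay: no kept pair within a window exceeds r2_max
  ld_block <- base[, rep(1:3, each = 4)] +
    matrix(rbinom(200 * 12, 1, 0.1), 200, 12)
  colnames(ld_block) <- paste0("b", 1:12)
  res3 <- ld_prune(ld_block, window = 12, step = 12)
  kept <- ld_block[, res3$kept, drop = FALSE]
  if (ncol(kept) > 1) {
    r2 <- cor(kept)^2
    diag(r2) <- 0
    expect_lte(max(r2), 0.2 + 1e-12)
  }
  # monomorphic SNPs dropped with a flag
  mono <- cbind(base, zero = 0L)
  expect_true("zero" %in% ld_prune(mono)$monomorphic)
})

test_that("build_linkage_map keeps the max-heterozygosity SNP per window", {
  snps <- data.frame(key = c("a", "b", "c"), chrom = "1",
                     cM = c(0.1, 0.2, 0.5), af = c(0.3, 0.5, 0.2))
  out <- build_linkage_map(snps, window_cm = 0.3)
  # window 1 holds a,b: af 0.5 has het 0.5 > 0.42
  expect_equal(out$key, c("b", "c"))
  # tie on heterozygosity (af p vs 1-p): lowest MAF wins -> equal MAF,
  # then smallest position
  tie <- data.frame(key = c("x", "y"), chrom = "1", cM = c(0.0, 0.1),
                    af = c(0.4, 0.6))
  expect_equal(build_linkage_map(tie, 0.3)$key, "x")
  # at most one SNP per window; deterministic under permutation
  set.seed(3)
  many <- data.frame(key = sprintf("s%03d", 1:200), chrom = "1",
                     cM = sort(runif(200, 0, 20)),
                     af = runif(200, 0.05, 0.95))
  o1 <- build_linkage_map(many)
  o2 <- build_linkage_map(many[sample(200), ])
  expect_identical(o1$key, o2$key)
  wins <- floor((o1$cM - min(many$cM)) / 0.3)
  expect_false(any(duplicated(wins)))
})

test_that("a paper-scale synthetic SNP set retains roughly one SNP per occupied window", {
  # ~3500 cM genome; SNPs dense enough to occupy most 0.3 cM windows
  set.seed(17)
  cms <- sort(runif(30000, 0, 3500))
  snps <- data.frame(key = sprintf("r%05d", seq_along(cms)), chrom = "g",
                     cM = cms, af = runif(length(cms), 0.05, 0.95))
  out <- build_linkage_map(snps)
  occupied <- length(unique(floor((cms - cms[1]) / 0.3)))
  expect_equal(nrow(out), occupied)
  # with this density the retained count sits near the ~5900 scale of a
  # genome-wide 0.3 cM map
  expect_gt(nrow(out), 5000)
  expect_lt(nrow(out), 3500 / 0.3 + 1)
})

test_that("trim_pedigree keeps affecteds plus connecting ancestors", {
  fam <- nuclear_family("T", 3, c("CD", "CD", "unaffected"))
  res <- trim_pedigree(fam, "CD")
  expect_true(res$informative)
  expect_setequal(res$family$id, c("T_p1", "T_p2", "T_c1", "T_c2"))
  # single affected -> non-informative
  solo <- nuclear_family("S", 2, c("CD", "unaffected"))
  expect_false(trim_pedigree(solo, "CD")$informative)
  # UC-only family informative for IBD but not CD
  uc <- nuclear_family("U", 2, c("UC", "UC"))
  expect_true(trim_pedigree(uc, "IBD")$informative)
  expect_false(trim_pedigree(uc, "CD")$informative)
})

test_that("select_loci finds maximal runs above threshold with true peaks", {
  grid <- data.frame(chrom = "16", bp = seq(1e6, 2e6, by = 1e5),
                     cM = seq(1, 2, by = 0.1), lod = 1.0)
  expect_equal(nrow(select_loci(grid)), 0)      # flat below threshold
  grid$lod[5:7] <- c(1.6, 2.074, 1.8)
  loci <- select_loci(grid)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$peak_lod, 2.074)
  expect_equal(loci$start_bp, grid$bp[5])
  # two disjoint peaks on different chromosomes
  g2 <- rbind(
    data.frame(chrom = "9", bp = 1:5 * 1e5, cM = 1:5, lod = c(1, 1.741, 1.741, 1, 1)),
    data.frame(chrom = "13", bp = 1:5 * 1e5, cM = 1:5, lod = c(1, 1, 1.873, 1.873, 1)))
  loci2 <- select_loci(g2)
  expect_equal(nrow(loci2), 2)
  expect_setequal(loci2$peak_lod, c(1.741, 1.873))
})

test_that("contributing_families uses strictly positive mean LOD", {
  locus <- data.frame(chrom = "16", start_bp = 1e6, end_bp = 2e6,
                      peak_lod = 2)
  tab <- data.frame(family_id = c("A", "B", "C"), chrom = "16",
                    start_bp = 1e6, end_bp = 2e6, lod = c(0.3, 0, -0.2))
  expect_equal(contributing_families(tab, locus), "A")
  tab$lod <- c(-1, -0.5, -0.1)
  expect_length(contributing_families(tab, locus), 0)
  # family with no values at the locus excluded with warning
  tab2 <- rbind(tab[1:2, ],
                data.frame(family_id = "D", chrom = "2", start_bp = 1,
                           end_bp = 2, lod = 5))
  tab2$lod[1] <- 0.4
  expect_warning(res <- contributing_families(tab2, locus), "excluded")
  expect_equal(res, "A")
})

test_that("linkage_shared_variants applies the two-family sharing rule", {
  # three families, planted variant carried by 2 affecteds in each of
  # FAM1..FAM3; another variant only in FAM1
  co <- make_cohort(list(c("CD", "CD", "unaffected"),
                         c("CD", "CD"), c("CD", "CD"),
                         c("CD", "CD")))
  samples <- co$individuals$id
  g <- matrix(0L, length(samples), 2, dimnames = list(samples, NULL))
  for (f in c("FAM1", "FAM2", "FAM3"))
    g[paste0(f, c("_c1", "_c2")), 1] <- 1L
  g[paste0("FAM1", c("_c1", "_c2")), 2] <- 1L
  vs <- make_vs(g, af = 0.01, gene = c("NOD2", "NOD2"),
                pos = c(1500, 1600))
  loci <- data.frame(chrom = "1", start_bp = 1000, end_bp = 2000,
                     peak_lod = 2.074)
  genes <- data.frame(gene = "NOD2", chrom = "1", start = 1400, end = 1700)
  # FAM1..3 contribute; FAM4 does not
  lod <- data.frame(family_id = paste0("FAM", 1:4), chrom = "1",
                    start_bp = 1000, end_bp = 2000,
                    lod = c(0.5, 0.4, 0.3, -0.2))
  hits <- linkage_shared_variants(vs, loci, co, lod, genes, "CD")
  expect_equal(hits$key, vs$variants$key[1])
  expect_equal(hits$n_families, 3)
  # removing a contributing family can only shrink the output
  lod2 <- lod; lod2$lod[2] <- -1
  hits2 <- linkage_shared_variants(vs, loci, co, lod2, genes, "CD")
  expect_true(all(hits2$key %in% hits$key))
  expect_equal(hits2$n_families, 2)
  # common variant excluded by the AF ceiling
  vs$variants$af_aj <- vs$variants$af_nfe <- vs$variants$af_paj <- 0.1
  expect_equal(nrow(linkage_shared_variants(vs, loci, co, lod, genes, "CD")), 0)
})
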