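#' Two-sided Fisher's exact test on a 2x2 allele-count table
#'
#' The two-sided p sums, over all tables with the observed margins, the
#' hypergeometric probabilities no greater than that of the observed
#' table (the standard convention, not mid-p). The odds ratio is the
#' sample cross-product; when any cell is zero a 0.5 continuity
#' correction is applied to all cells and the estimate flagged.
#'
#' @param case_alt,case_ref,ctrl_alt,ctrl_ref allele counts.
#' @return list with `p`, `or`, `or_corrected` (continuity correction
#'   used?), `undefined` (no alternate alleles anywhere).
#' @export
fisher_allele_test <- function(case_alt, case_ref, ctrl_alt, ctrl_ref) {
  counts <- c(case_alt, case_ref, ctrl_alt, ctrl_ref)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (case_alt + case_ref == 0 || ctrl_alt + ctrl_ref == 0)
    stop("empty margin")
  if (case_alt == 0 && ctrl_alt == 0)
    return(list(p = 1, or = NA_real_, or_corrected = FALSE,
                undefined = TRUE))
  p <- .fisher_p(case_alt, case_ref, ctrl_alt, ctrl_ref)
  if (any(counts == 0)) {
    or <- ((case_alt + 0.5) * (ctrl_ref + 0.5)) /
      ((case_ref + 0.5) * (ctrl_alt + 0.5))
    corrected <- TRUE
  } else {
    or <- (case_alt * ctrl_ref) / (case_ref * ctrl_alt)
    corrected <- FALSE
  }
  list(p = p, or = or, or_corrected = corrected, undefined = FALSE)
}

# scalar two-sided Fisher p via hypergeometric summation
.fisher_p <- function(a, b, c, d) {
  m <- a + b          # case alleles
  k <- a + c          # alt alleles
  lo <- max(0L, k - (c + d))
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, c + d, k)
  sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
}

# vectorized over replicates (used by the power simulation)
.fisher_p_vec <- function(a, b, c, d) {
  vapply(seq_along(a), function(i) .fisher_p(a[i], b[i], c[i], d[i]), 0)
}

#' Pick the phenotype with the minimum replication p-value
#'
#' @param results data.frame with columns `phenotype` (IBD/CD/UC), `p`
#'   and any other statistics; one row per phenotype.
#' @param tie_order preference order when p-values tie.
#' @return the selected row, with `min_p_phenotype` recorded.
#' @export
min_phenotype_result <- function(results,
                                 tie_order = c("IBD", "CD", "UC")) {
  if (nrow(results) == 0) stop("no phenotype results")
  o <- order(results$p, match(results$phenotype, tie_order))
  out <- results[o[1], , drop = FALSE]
  out$min_p_phenotype <- out$phenotype
  out
}

#' Simulation-based power of the case/control Fisher test
#'
#' Derives the case AF from the control AF and odds ratio on the odds
#' scale, draws allele counts Binomial(2n, AF) for each arm, applies
#' [fisher_allele_test()], and reports the fraction of replicates
#' significant at `alpha`. Optionally the log odds ratio is redrawn per
#' replicate from Normal(log OR, `log_or_sd`).
#'
#' @param control_af population control allele frequency, in (0, 1).
#' @param odds_ratio allelic odds ratio (> 0).
#' @param n_cases,n_controls cohort sizes (individuals; 2n alleles).
#' @param alpha significance level.
#' @param n_sims replicates (default 10000).
#' @param log_or_sd standard deviation for sampled log odds ratios
#'   (default 0 = fixed OR).
#' @return estimated power.
#' @export
cc_power <- function(control_af, odds_ratio, n_cases, n_controls, alpha,
                     n_sims = 10000L, log_or_sd = 0) {
  stopifnot(control_af > 0, control_af < 1, odds_ratio > 0,
            alpha > 0, alpha < 1)
  or <- if (log_or_sd > 0)
    exp(stats::rnorm(n_sims, log(odds_ratio), log_or_sd))
  else rep(odds_ratio, n_sims)
  odds_case <- or * control_af / (1 - control_af)
  case_af <- odds_case / (1 + odds_case)
  if (any(case_af >= 1)) stop("case AF >= 1 under this odds ratio")
  ca <- stats::rbinom(n_sims, 2L * n_cases, case_af)
  oa <- stats::rbinom(n_sims, 2L * n_controls, control_af)
  p <- .fisher_p_vec(ca, 2L * n_cases - ca, oa, 2L * n_controls - oa)
  mean(p < alpha)
}

#' Smallest odds ratio reaching a target power
#'
#' Bisection on the odds ratio against [cc_power()]; each power
#' evaluation reuses the same RNG substream (common random numbers) so
#' the power curve seen by the bisection is monotone in OR up to
#' binomial noise. The result is reported to one decimal place.
#'
#' @inheritParams cc_power
#' @param target target power (default 0.80).
#' @param or_max search cap (default 50).
#' @param seed seed for the common random numbers (default 1).
#' @param tol bisection half-width on the OR scale (default 0.02).
#' @return list with `or` (1-dp), `or_raw`, `power_at_or`, `unreachable`.
#' @export
find_or_for_power <- function(control_af, n_cases, n_controls, alpha,
                              target = 0.80, n_sims = 10000L,
                              or_max = 50, seed = 1L, tol = 0.02) {
  stopifnot(target > 0, target < 1)
  eval_power <- function(or) {
    set.seed(seed)
    cc_power(control_af, or, n_cases, n_controls, alpha, n_sims)
  }
  lo <- 1; hi <- 2
  while (eval_power(hi) < target) {
    lo <- hi; hi <- hi * 2
    if (hi > or_max)
      return(list(or = NA_real_, or_raw = NA_real_,
                  power_at_or = eval_power(or_max), unreachable = TRUE))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (eval_power(mid) >= target) hi <- mid else lo <- mid
  }
  or_raw <- (lo + hi) / 2
  list(or = round(or_raw, 1), or_raw = or_raw,
       power_at_or = eval_power(hi), unreachable = FALSE)
}

#' Count the effective number of correlated datasets
#'
#' Datasets whose p-values over shared variants are significantly
#' rank-correlated (Spearman, pairwise p < `sig_level`) are merged into
#' one effective dataset; the effective count is the number of connected
#' components.
#'
#' @param pvalue_matrix variants x datasets matrix of p-values (NA where
#'   a variant was not tested in a dataset).
#' @param sig_level Spearman significance level for merging (default
#'   0.05).
#' @param min_shared minimum shared variants per pair (default 3).
#' @return list with `n_effective`, `components` (dataset -> component
#'   id), `pair_p` (matrix of Spearman p-values).
#' @export
effective_dataset_count <- function(pvalue_matrix, sig_level = 0.05,
                                    min_shared = 3L) {
  m <- as.matrix(pvalue_matrix)
  k <- ncol(m)
  if (k < 2) stop("need at least two datasets")
  nm <- colnames(m) %||% paste0("D", seq_len(k))
  pair_p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  comp <- seq_len(k)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(m[, c(i, j)])
    if (sum(ok) < min_shared) {
      warning("pair ", nm[i], "~", nm[j], ": fewer than ", min_shared,
              " shared variants; skipped")
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(m[ok, i], m[ok, j], method = "spearman"))
    pair_p[i, j] <- pair_p[j, i] <- ct$p.value
    if (ct$p.value < sig_level) comp[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(k), find, 0L)
  list(n_effective = length(unique(roots)),
       components = stats::setNames(match(roots, unique(roots)), nm),
       pair_p = pair_p)
}

#' Multiple-testing budget and Bonferroni threshold
#'
#' Total tests = (linkage variants x effective case/control datasets) +
#' (family-prioritized variants x (effective case/control + effective
#' gene-drop datasets)); the threshold is 0.05 / total.
#'
#' @param n_linkage_variants variants from the linkage route.
#' @param n_rare_variants variants from the family-based route.
#' @param eff_cc_datasets effective case/control dataset count.
#' @param eff_gd_datasets effective gene-dropping dataset count.
#' @param family_wise family-wise error rate (default 0.05).
#' @return list of class `test_budget` with `total_tests` and `alpha`.
#' @export
test_budget <- function(n_linkage_variants, n_rare_variants,
                        eff_cc_datasets, eff_gd_datasets,
                        family_wise = 0.05) {
  total <- n_linkage_variants * eff_cc_datasets +
    n_rare_variants * (eff_cc_datasets + eff_gd_datasets)
  if (total < 1) stop("empty test budget")
  structure(list(n_linkage_variants = n_linkage_variants,
                 n_rare_variants = n_rare_variants,
                 eff_cc_datasets = eff_cc_datasets,
                 eff_gd_datasets = eff_gd_datasets,
                 total_tests = total, alpha = family_wise / total),
            class = "test_budget")
}

#' @rdname test_budget
#' @param budget a `test_budget`.
#' @return `bonferroni_threshold`: the corrected significance level.
#' @export
bonferroni_threshold <- function(budget) budget$alpha

#' Significant variants at a threshold
#'
#' @param results data.frame with `key` and `min_p` columns.
#' @param alpha significance threshold.
#' @return list with `n` and `keys` of variants with `min_p < alpha`.
#' @export
count_significant <- function(results, alpha) {
  if (nrow(results) == 0) return(list(n = 0L, keys = character(0)))
  sel <- !is.na(results$min_p) & results$min_p < alpha
  list(n = sum(sel), keys = results$key[sel])
}

#' Compare two allele-frequency distributions
#'
#' Two-sided Wilcoxon rank-sum test.
#'
#' @param afs_a,afs_b numeric AF vectors.
#' @return two-sided p-value.
#' @export
compare_af_distributions <- function(afs_a, afs_b) {
  stopifnot(length(afs_a) > 0, length(afs_b) > 0)
  stats::wilcox.test(afs_a, afs_b, exact = FALSE)$p.value
}
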