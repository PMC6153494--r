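#' Gene-drop a variant through one family
#'
#' Founders receive a genotype drawn from Binomial(2, `founder_af`);
#' alleles are then transmitted down the pedigree, heterozygous parents
#' passing either allele with probability 1/2. Equivalent to a
#' depth-first traversal from each founder couple, vectorized over
#' `n_reps` independent replicates.
#'
#' @param family a `family_ped`.
#' @param founder_af founder (population) allele frequency in \[0, 1\].
#' @param n_reps number of independent replicates (default 1).
#' @return integer matrix of dosages, members x replicates, rownames =
#'   member ids.
#' @export
drop_family <- function(family, founder_af, n_reps = 1L) {
  stopifnot(founder_af >= 0, founder_af <= 1, n_reps >= 1)
  fam <- as_family_ped(family)   # topological order; errors on cycles
  n <- nrow(fam)
  fa <- match(fam$father_id, fam$id)
  mo <- match(fam$mother_id, fam$id)
  dos <- matrix(0L, n, n_reps, dimnames = list(fam$id, NULL))
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      dos[i, ] <- stats::rbinom(n_reps, 2L, founder_af)
    } else {
      transmit <- function(parent) {
        d <- dos[parent, ]
        # dosage 2 always transmits; dosage 1 transmits with prob 1/2
        as.integer(d == 2L) +
          as.integer(d == 1L) * stats::rbinom(n_reps, 1L, 0.5)
      }
      dos[i, ] <- transmit(fa[i]) + transmit(mo[i])
    }
  }
  dos
}

#' Gene-dropping configuration
#'
#' @param n_sims number of simulated replicates (default 100000).
#' @param seed RNG seed (`NULL` = leave the RNG state alone).
#' @param exclude_family index family id excluded from every simulated
#'   (and observed) cohort AF.
#' @param phenotype cases counted in the cohort AF (default IBD).
#' @return list of class `genedrop_config`.
#' @export
genedrop_config <- function(n_sims = 100000L, seed = NULL,
                            exclude_family = NULL, phenotype = "IBD") {
  stopifnot(n_sims >= 1)
  structure(list(n_sims = as.integer(n_sims), seed = seed,
                 exclude_family = exclude_family, phenotype = phenotype),
            class = "genedrop_config")
}

# sequenced phenotype-cases outside the excluded family
.genedrop_cases <- function(cohort, config) {
  ind <- cohort$individuals
  keep <- ind$sequenced & pheno_matches(ind$phenotype, config$phenotype)
  if (!is.null(config$exclude_family))
    keep <- keep & ind$family_id != config$exclude_family
  ind$id[keep]
}

#' Simulate the null distribution of the cohort allele frequency
#'
#' Drops the variant independently through every family in the cohort
#' (and assigns Binomial(2, af) genotypes to sporadic cases and other
#' singleton founders), then computes, per replicate, the allele
#' frequency among the sequenced phenotype-cases outside the index
#' family.
#'
#' @param cohort a `cohort`.
#' @param founder_af control (population) allele frequency.
#' @param config a [genedrop_config()].
#' @return list of class `genedrop_result`: `simulated_afs` (length
#'   `n_sims`), `n_case_alleles`, `cases`.
#' @export
simulate_cohort_af <- function(cohort, founder_af, config = genedrop_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cases <- .genedrop_cases(cohort, config)
  if (length(cases) == 0)
    stop("no sequenced cases outside the excluded family")
  ind <- cohort$individuals
  alt_total <- numeric(config$n_sims)
  fams <- unique(ind$family_id[ind$id %in% cases])
  # deterministic family order so results do not depend on table order
  for (f in sort(fams)) {
    fam <- as_family_ped(ind[ind$family_id == f, ])
    fam_cases <- intersect(fam$id, cases)
    if (nrow(fam) == 1) {
      alt_total <- alt_total + stats::rbinom(config$n_sims, 2L, founder_af)
    } else {
      dos <- drop_family(fam, founder_af, config$n_sims)
      alt_total <- alt_total +
        colSums(dos[fam_cases, , drop = FALSE])
    }
  }
  structure(list(simulated_afs = alt_total / (2 * length(cases)),
                 n_case_alleles = 2L * length(cases), cases = cases),
            class = "genedrop_result")
}

#' Observed cohort allele frequency for a variant
#'
#' Allele frequency among the same individuals a
#' [simulate_cohort_af()] null is computed over, so the comparison is
#' like for like.
#'
#' @param vs a `variant_set`.
#' @param key variant key.
#' @param cohort a `cohort`.
#' @param config a [genedrop_config()].
#' @return observed allele frequency.
#' @export
observed_cohort_af <- function(vs, key, cohort, config = genedrop_config()) {
  cases <- intersect(.genedrop_cases(cohort, config), rownames(vs$geno))
  j <- match(key, vs$variants$key)
  if (is.na(j)) stop("unknown variant key: ", key)
  g <- vs$geno[cases, j]
  sum(g, na.rm = TRUE) / (2 * sum(!is.na(g)))
}

#' Empirical gene-drop enrichment p-value
#'
#' p = (#\{simulated AF >= observed AF\} + 1) / (n_sims + 1); the +1
#' correction keeps p strictly positive, so 100,000 all-miss replicates
#' report p < 1e-5 rather than zero.
#'
#' @param observed_af observed cohort allele frequency.
#' @param result a `genedrop_result`.
#' @return empirical p-value in (0, 1].
#' @export
genedrop_pvalue <- function(observed_af, result) {
  if (observed_af < 0 || observed_af > 1)
    stop("observed_af outside [0, 1]")
  sims <- result$simulated_afs
  (sum(sims >= observed_af) + 1) / (length(sims) + 1)
}

#' Gene-drop a variant and test for cohort enrichment
#'
#' Convenience wrapper: builds the null with [simulate_cohort_af()],
#' measures the observed AF over the same cases, and returns the
#' empirical p.
#'
#' @inheritParams observed_cohort_af
#' @param founder_af control AF used to seed founders.
#' @return `genedrop_result` with `observed_af` and `p_value` fields
#'   added.
#' @export
genedrop_test <- function(vs, key, cohort, founder_af,
                          config = genedrop_config()) {
  res <- simulate_cohort_af(cohort, founder_af, config)
  res$observed_af <- observed_cohort_af(vs, key, cohort, config)
  res$p_value <- genedrop_pvalue(res$observed_af, res)
  res
}

#' Normal-approximation power of the gene-drop test
#'
#' For each hypothesized cohort AF, the proportion q of null-simulated
#' AFs below it is treated as a Binomial(n_sims, q) count and
#' approximated by a Normal distribution; power is the probability that
#' the observed proportion of sub-threshold simulations reaches
#' 1 - alpha.
#'
#' @param result a `genedrop_result` (the null distribution).
#' @param cohort_af_grid hypothesized cohort AFs.
#' @param alpha significance level.
#' @return data.frame with `cohort_af`, `q` and `power`.
#' @export
genedrop_power <- function(result, cohort_af_grid, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  sims <- result$simulated_afs
  n <- length(sims)
  power <- vapply(cohort_af_grid, function(af) {
    q <- mean(sims < af)
    if (q == 0) return(0)
    if (q == 1) return(1)
    # K ~ Binomial(n, q) ~ Normal(nq, nq(1-q)); power = P(K/n >= 1 - alpha)
    stats::pnorm(n * (1 - alpha), mean = n * q,
                 sd = sqrt(n * q * (1 - q)), lower.tail = FALSE)
  }, 0)
  data.frame(cohort_af = cohort_af_grid,
             q = vapply(cohort_af_grid, function(af) mean(sims < af), 0),
             power = power)
}
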