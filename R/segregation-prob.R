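# Exact conditional genotype probabilities under the single-carrier-founder
# model: the variant enters the pedigree as one copy, heterozygous, in
# exactly one founder; all transmissions are fair Mendelian coin flips.

# Enumerate the joint probability of observing `constraints` (named dosage
# vector) given carrier founder `f` carries one copy and all other
# founders carry none. Returns the total probability mass of transmission
# patterns matching every constrained individual.
.single_founder_prob <- function(fam, f, constraints) {
  n <- nrow(fam)
  fa <- match(fam$father_id, fam$id)
  mo <- match(fam$mother_id, fam$id)
  obs <- constraints[match(fam$id, names(constraints))]
  total <- 0
  dos <- integer(n)
  recurse <- function(i, prob) {
    if (prob == 0) return()
    if (i > n) {
      total <<- total + prob
      return()
    }
    if (is.na(fa[i])) {
      d_opts <- if (fam$id[i] == f) 1L else 0L
      p_opts <- 1
    } else {
      cf <- dos[fa[i]]; cm <- dos[mo[i]]
      # transmitted copies from each het parent are independent fair coins;
      # dosage-2 parents always transmit (cannot occur under one founder
      # copy unless the pedigree loops, handled for generality)
      pf <- cf / 2; pm <- cm / 2
      d_opts <- 0:2
      p_opts <- c((1 - pf) * (1 - pm), pf * (1 - pm) + (1 - pf) * pm,
                  pf * pm)
      keep <- p_opts > 0
      d_opts <- d_opts[keep]; p_opts <- p_opts[keep]
    }
    for (k in seq_along(d_opts)) {
      if (!is.na(obs[i]) && d_opts[k] != obs[i]) next
      dos[i] <<- d_opts[k]
      recurse(i + 1, prob * p_opts[k])
    }
    dos[i] <<- 0L
  }
  recurse(1L, 1)
  total
}

#' Conditional probability of unaffected genotypes given affected ones
#'
#' Computes P(unaffected genotype vector | affected genotype vector)
#' under the model that the variant descends from a single heterozygous
#' carrier founder (uniform prior over founders consistent with the
#' observed affected genotypes) with fair Mendelian transmission, by
#' exhaustive enumeration of founder assignments and transmission
#' patterns.
#'
#' @param family a `family_ped`.
#' @param affected_genotypes named dosage vector (ids -> 0/1) for the
#'   observed affected individuals; observed carriers must be
#'   heterozygous (dosage 1).
#' @param unaffected_genotypes named dosage vector for the unaffected
#'   individuals whose joint probability is wanted.
#' @return probability in \[0, 1\].
#' @export
conditional_unaffected_prob <- function(family, affected_genotypes,
                                        unaffected_genotypes) {
  fam <- as_family_ped(family)
  if (any(affected_genotypes > 1))
    stop("observed affected carriers must be heterozygous")
  bad <- setdiff(c(names(affected_genotypes), names(unaffected_genotypes)),
                 fam$id)
  if (length(bad) > 0) stop("ids not in family: ", paste(bad, collapse = ", "))
  founders <- fam$id[is.na(fam$father_id)]
  p_aff <- vapply(founders, function(f)
    .single_founder_prob(fam, f, affected_genotypes), 0)
  if (all(p_aff == 0))
    stop_famrvar("no single carrier founder is consistent with the observed affected genotypes",
                 "famrvar_inconsistent_pedigree")
  both <- c(affected_genotypes, unaffected_genotypes)
  p_both <- vapply(founders, function(f)
    .single_founder_prob(fam, f, both), 0)
  # uniform prior over consistent founders cancels to a ratio of sums
  consistent <- p_aff > 0
  sum(p_both[consistent]) / sum(p_aff[consistent])
}

#' Power of the within-family segregation test
#'
#' The most extreme observable outcome is that none of the eligible
#' unaffected individuals carries the variant; its conditional
#' probability given the affected genotypes is the smallest attainable
#' p-value. The family has power at level `alpha` only when that minimum
#' falls below `alpha`.
#'
#' @param family a `family_ped`.
#' @param affected_genotypes named dosage vector for observed affected
#'   carriers (see [conditional_unaffected_prob()]).
#' @param phenotype analysis phenotype for eligibility (default IBD).
#' @param alpha significance level (default 0.05).
#' @param unaffected_ids override the eligible unaffected set.
#' @return list with `has_power` (logical), `min_p` (the all-non-carrier
#'   conditional probability) and `n_unaffected`.
#' @export
segregation_power <- function(family, affected_genotypes,
                              phenotype = "IBD", alpha = 0.05,
                              unaffected_ids = NULL) {
  fam <- as_family_ped(family)
  ids <- unaffected_ids %||% eligible_unaffecteds(fam, phenotype)
  if (length(ids) == 0)
    return(list(has_power = FALSE, min_p = 1, n_unaffected = 0L))
  zero <- stats::setNames(rep(0L, length(ids)), ids)
  min_p <- conditional_unaffected_prob(fam, affected_genotypes, zero)
  list(has_power = min_p < alpha, min_p = min_p,
       n_unaffected = length(ids))
}
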