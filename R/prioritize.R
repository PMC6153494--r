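#' Sharing and segregation count rules
#'
#' The two count-level rules applied throughout family prioritization:
#' a variant is shared when carried by at least `frac` (default 75%) of
#' the evaluable affected individuals of a family, and segregates
#' acceptably when at most `frac_unaff` (default 1/3) of the eligible
#' unaffected individuals carry it. Boundaries are inclusive in both
#' cases (6/8 affecteds pass at 0.75; 3/9 unaffecteds pass at 1/3).
#'
#' @param n_carriers carriers among the group.
#' @param n_total evaluable group size.
#' @param frac minimum affected-carrier fraction.
#' @return logical.
#' @export
passes_sharing <- function(n_carriers, n_total, frac = 0.75) {
  stopifnot(all(n_total > 0), all(n_carriers <= n_total))
  n_carriers / n_total >= frac
}

#' @rdname passes_sharing
#' @param frac_unaff maximum unaffected-carrier fraction.
#' @export
passes_segregation <- function(n_carriers, n_total, frac_unaff = 1 / 3) {
  stopifnot(all(n_total > 0), all(n_carriers <= n_total))
  n_carriers / n_total <= frac_unaff
}

#' Select large families (lfams) for a phenotype
#'
#' An lfam for phenotype P is a family with at least `min_affected`
#' sequenced P-affected members (CD counts toward IBD).
#'
#' @param cohort a `cohort`.
#' @param phenotype `"IBD"` or `"CD"` (or `"UC"`).
#' @param min_affected minimum sequenced affected count (default 4).
#' @param include_ibdu_in_cd see [pheno_matches()].
#' @return character vector of family ids.
#' @export
select_lfams <- function(cohort, phenotype = "IBD", min_affected = 4L,
                         include_ibdu_in_cd = FALSE) {
  fams <- family_ids(cohort)
  n_aff <- vapply(fams, function(f)
    length(affected_members(get_family(cohort, f), phenotype,
                            include_ibdu_in_cd)), 0L)
  fams[n_aff >= min_affected]
}

#' Affected-carrier fraction of a variant within a family
#'
#' The denominator counts sequenced phenotype-affected members with a
#' non-missing genotype; exclusions for missingness are flagged.
#'
#' @param vs a `variant_set`.
#' @param key variant key.
#' @param family a `family_ped`.
#' @param phenotype analysis phenotype.
#' @return one-row data.frame: `key`, `family_id`, `phenotype`,
#'   `n_affected_carriers`, `n_affected`, `fraction`, `passes_75`,
#'   `had_missing`.
#' @export
family_carrier_fraction <- function(vs, key, family, phenotype = "IBD") {
  fam <- as_family_ped(family)
  j <- match(key, vs$variants$key)
  if (is.na(j)) stop("unknown variant key: ", key)
  aff <- intersect(affected_members(fam, phenotype), rownames(vs$geno))
  g <- vs$geno[aff, j]
  evaluable <- !is.na(g)
  if (!any(evaluable))
    stop_famrvar(paste0("no evaluable affected genotypes for ", key,
                        " in family ", fam$family_id[1]),
                 "famrvar_no_affected")
  n_aff <- sum(evaluable)
  n_car <- sum(g[evaluable] >= 1)
  data.frame(key = key, family_id = fam$family_id[1], phenotype = phenotype,
             n_affected_carriers = n_car, n_affected = n_aff,
             fraction = n_car / n_aff,
             passes_75 = passes_sharing(n_car, n_aff),
             had_missing = any(!evaluable), stringsAsFactors = FALSE)
}

#' Prioritize very rare damaging variants shared within lfams
#'
#' Applies the family-based rule: a variant qualifies when it is very
#' rare in the population (control AF < `af_max`, default 0.005),
#' damaging, and carried by at least 75% of the sequenced affected
#' members of at least one lfam.
#'
#' @param vs annotated, oriented, QC-passed `variant_set`.
#' @param cohort a `cohort`.
#' @param phenotype analysis phenotype (lfams and affecteds follow it).
#' @param min_affected lfam threshold (default 4).
#' @param af_max control-AF ceiling (default 0.005).
#' @return data.frame, one row per qualifying variant: annotation,
#'   `control_af`, `n_lfams` (distinct passing lfams) and their ids.
#' @export
prioritize_rare_family_variants <- function(vs, cohort, phenotype = "IBD",
                                            min_affected = 4L,
                                            af_max = 0.005) {
  lfams <- select_lfams(cohort, phenotype, min_affected)
  v <- vs$variants
  caf <- control_af(v$af_aj, v$af_nfe, v$af_paj,
                    if ("af_aj_wgs" %in% names(v)) v$af_aj_wgs else NA,
                    context = "filtering")
  cand <- which(is_damaging(v$consequence, v$carol, v$cadd) &
                  !caf$af_unknown & caf$control_af < af_max)
  out <- list()
  for (j in cand) {
    hits <- character(0)
    for (f in lfams) {
      fam <- get_family(cohort, f)
      res <- tryCatch(
        family_carrier_fraction(vs, v$key[j], fam, phenotype),
        famrvar_no_affected = function(e) NULL)
      if (!is.null(res) && res$passes_75) hits <- c(hits, f)
    }
    if (length(hits) > 0)
      out[[length(out) + 1]] <- data.frame(
        key = v$key[j],
        gene = if ("gene" %in% names(v)) v$gene[j] else NA_character_,
        consequence = v$consequence[j], control_af = caf$control_af[j],
        phenotype = phenotype, n_lfams = length(hits),
        lfams = paste(hits, collapse = ","), stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(key = character(0), gene = character(0),
                      consequence = character(0), control_af = numeric(0),
                      phenotype = character(0), n_lfams = integer(0),
                      lfams = character(0)))
  do.call(rbind, out)
}

# eligible unaffecteds for segregation: sequenced unaffected siblings or
# offspring of affecteds, excluding parents of any affected (obligate
# carrier proxy)
eligible_unaffecteds <- function(family, phenotype = "IBD") {
  fam <- as_family_ped(family)
  aff <- fam$id[pheno_matches(fam$phenotype, phenotype)]
  aff_parents <- unique(stats::na.omit(
    c(fam$father_id[fam$id %in% aff], fam$mother_id[fam$id %in% aff])))
  unaff <- fam[fam$sequenced & fam$phenotype == "unaffected" &
                 !(fam$id %in% aff_parents), ]
  # sibling of an affected: shares at least one parent; offspring: a
  # parent is affected
  is_sib <- !is.na(unaff$father_id) &
    (paste(unaff$father_id, unaff$mother_id) %in%
       paste(fam$father_id[fam$id %in% aff], fam$mother_id[fam$id %in% aff]) |
       unaff$father_id %in% fam$father_id[fam$id %in% aff] |
       unaff$mother_id %in% fam$mother_id[fam$id %in% aff])
  is_off <- unaff$father_id %in% aff | unaff$mother_id %in% aff
  unaff$id[is_sib | is_off]
}

#' Segregation filter against unaffected relatives
#'
#' Counts carriers among the eligible unaffected individuals — sequenced
#' unaffected siblings or offspring of affecteds, with parents of
#' affecteds excluded as potential obligate carriers — and applies the
#' at-most-one-third rule. Families with fewer than `min_unaffected`
#' eligible unaffecteds are skipped with a reason.
#'
#' @param vs a `variant_set`.
#' @param key variant key.
#' @param family a `family_ped`.
#' @param phenotype analysis phenotype.
#' @param min_unaffected minimum eligible unaffecteds (default 2).
#' @return one-row data.frame: `key`, `family_id`,
#'   `n_unaffected_carriers`, `n_unaffected`, `passes_third`, `skipped`,
#'   `skip_reason`.
#' @export
segregation_filter <- function(vs, key, family, phenotype = "IBD",
                               min_unaffected = 2L) {
  fam <- as_family_ped(family)
  elig <- intersect(eligible_unaffecteds(fam, phenotype), rownames(vs$geno))
  j <- match(key, vs$variants$key)
  if (is.na(j)) stop("unknown variant key: ", key)
  g <- vs$geno[elig, j]
  elig <- elig[!is.na(g)]
  g <- g[!is.na(g)]
  if (length(elig) < min_unaffected)
    return(data.frame(key = key, family_id = fam$family_id[1],
                      n_unaffected_carriers = NA_integer_,
                      n_unaffected = length(elig), passes_third = NA,
                      skipped = TRUE,
                      skip_reason = "fewer than 2 eligible unaffecteds",
                      stringsAsFactors = FALSE))
  n_car <- sum(g >= 1)
  data.frame(key = key, family_id = fam$family_id[1],
             n_unaffected_carriers = n_car, n_unaffected = length(elig),
             passes_third = passes_segregation(n_car, length(elig)),
             skipped = FALSE, skip_reason = "", stringsAsFactors = FALSE)
}
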