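#' Pedigree cohort container
#'
#' A `cohort` wraps a table of individuals with parent links, sex,
#' phenotype subtype and sequencing status. Multi-member family ids define
#' families; affected singletons are sporadic cases and unaffected
#' singletons are controls.
#'
#' @name cohort
NULL

#' Construct a cohort from an individual table
#'
#' Validates pedigree structure: parent references must resolve (parents
#' referenced but absent from the table are synthesized as
#' unknown-phenotype, unsequenced founders), every non-founder has exactly
#' two parents, and each family graph is acyclic.
#'
#' @param individuals data.frame with columns `id`, `family_id`,
#'   `father_id`, `mother_id` (NA for founders), `sex`
#'   (`male`/`female`/`unknown`), `phenotype`
#'   (`CD`/`UC`/`IBDU`/`unaffected`/`unknown`), `sequenced` (logical).
#' @return object of class `cohort`.
#' @export
new_cohort <- function(individuals) {
  req <- c("id", "family_id", "father_id", "mother_id", "sex",
           "phenotype", "sequenced")
  missing_cols <- setdiff(req, names(individuals))
  if (length(missing_cols) > 0)
    stop("individual table lacks columns: ", paste(missing_cols, collapse = ", "))
  ind <- as.data.frame(individuals)[, req]
  ind$id <- as.character(ind$id)
  ind$family_id <- as.character(ind$family_id)
  ind$father_id <- as.character(ind$father_id)
  ind$mother_id <- as.character(ind$mother_id)
  ind$father_id[!is.na(ind$father_id) & ind$father_id %in% c("0", "")] <- NA
  ind$mother_id[!is.na(ind$mother_id) & ind$mother_id %in% c("0", "")] <- NA
  if (anyDuplicated(ind$id))
    stop("duplicate individual ids: ",
         paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "))
  bad_pheno <- setdiff(unique(ind$phenotype), PHENOTYPE_LEVELS)
  if (length(bad_pheno) > 0)
    stop("unknown phenotype codes: ", paste(bad_pheno, collapse = ", "))

  one_parent <- xor(is.na(ind$father_id), is.na(ind$mother_id))
  if (any(one_parent))
    stop_famrvar(
      paste0("individuals with exactly one parent listed: ",
             paste(ind$id[one_parent], collapse = ", ")),
      "famrvar_one_parent")

  # materialize referenced-but-absent parents as unknown founders
  for (col in c("father_id", "mother_id")) {
    ref <- setdiff(stats::na.omit(unique(ind[[col]])), ind$id)
    if (length(ref) > 0) {
      fam_of <- vapply(ref, function(p) ind$family_id[match(p, ind[[col]])], "")
      ind <- rbind(ind, data.frame(
        id = ref, family_id = fam_of, father_id = NA_character_,
        mother_id = NA_character_,
        sex = if (col == "father_id") "male" else "female",
        phenotype = "unknown", sequenced = FALSE,
        stringsAsFactors = FALSE))
    }
  }

  # structural checks per family: parents in same family, acyclic
  for (fid in unique(ind$family_id)) {
    fam <- ind[ind$family_id == fid, ]
    pref <- stats::na.omit(c(fam$father_id, fam$mother_id))
    if (!all(pref %in% fam$id))
      stop_famrvar(paste0("family ", fid,
                          ": parent ids cross family boundaries"),
                   "famrvar_structure")
    ped_topological_order(fam)  # errors on cycles
  }

  ind$founder <- is.na(ind$father_id) & is.na(ind$mother_id)
  nmem <- table(ind$family_id)
  ind$role <- ifelse(nmem[ind$family_id] > 1, "family",
                     ifelse(pheno_matches(ind$phenotype, "IBD"),
                            "sporadic_case",
                            ifelse(ind$phenotype == "unaffected",
                                   "control", "unknown")))
  rownames(ind) <- NULL
  structure(list(individuals = ind), class = "cohort")
}

# Topological order of a family table (founders first). Errors on cycles
# (including an individual listed as its own ancestor).
ped_topological_order <- function(fam) {
  ids <- fam$id
  order_out <- character(0)
  placed <- structure(rep(FALSE, nrow(fam)), names = ids)
  remaining <- ids
  repeat {
    ready <- vapply(remaining, function(i) {
      r <- fam[match(i, fam$id), ]
      (is.na(r$father_id) || placed[[r$father_id]]) &&
        (is.na(r$mother_id) || placed[[r$mother_id]])
    }, TRUE)
    if (!any(ready)) {
      if (length(remaining) == 0) break
      stop_famrvar(
        paste0("cyclic pedigree involving: ",
               paste(remaining, collapse = ", ")),
        "famrvar_cycle")
    }
    # sort each layer by id: a canonical order, so downstream stochastic
    # traversals do not depend on input row order
    order_out <- c(order_out, sort(remaining[ready]))
    placed[remaining[ready]] <- TRUE
    remaining <- remaining[!ready]
    if (length(remaining) == 0) break
  }
  order_out
}

#' Read a pedigree file into a cohort
#'
#' Expects a whitespace-delimited PLINK-style file with columns
#' `FID IID PAT MAT SEX PHENO [SUBTYPE] [SEQ]`. `PHENO` uses `1` =
#' unaffected, `2` = affected, `0`/`-9` = unknown. Column 7, when present,
#' gives the disease subtype of affecteds (`CD`, `UC` or `IBDU`; `.` or
#' `NA` allowed otherwise; an affected with no subtype is recorded as
#' `IBDU`). Column 8, when present, flags exome-sequenced individuals
#' (`1`/`0`); all individuals default to sequenced.
#'
#' @param path pedigree file path.
#' @return a [new_cohort()] object.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#",
                           fill = TRUE)
  if (ncol(tab) < 6)
    stop("pedigree file must have at least 6 columns, got ", ncol(tab))
  pheno_code <- tab[[6]]
  pheno <- rep("unknown", nrow(tab))
  pheno[pheno_code == "1"] <- "unaffected"
  pheno[pheno_code == "2"] <- "IBDU"  # affected, subtype refined below
  if (ncol(tab) >= 7) {
    sub <- toupper(tab[[7]])
    sub[is.na(sub) | sub %in% c(".", "NA", "0", "")] <- NA
    ok <- !is.na(sub) & pheno_code == "2"
    bad <- ok & !(sub %in% c("CD", "UC", "IBDU"))
    if (any(bad))
      stop("unknown subtype codes: ", paste(unique(sub[bad]), collapse = ", "))
    pheno[ok] <- sub[ok]
  }
  sequenced <- if (ncol(tab) >= 8) is.na(tab[[8]]) | tab[[8]] %in% c("", "1")
    else rep(TRUE, nrow(tab))
  sex <- c("1" = "male", "2" = "female")[tab[[5]]]
  sex[is.na(sex)] <- "unknown"
  new_cohort(data.frame(
    id = tab[[2]], family_id = tab[[1]],
    father_id = ifelse(tab[[3]] == "0", NA, tab[[3]]),
    mother_id = ifelse(tab[[4]] == "0", NA, tab[[4]]),
    sex = unname(sex), phenotype = pheno, sequenced = sequenced,
    stringsAsFactors = FALSE))
}

#' Write a cohort back to a pedigree file
#'
#' Inverse of [read_pedigree()]: emits the 8-column extended PED layout.
#'
#' @param cohort a `cohort`.
#' @param path output path.
#' @export
write_pedigree <- function(cohort, path) {
  ind <- cohort$individuals
  aff <- pheno_matches(ind$phenotype, "IBD")
  tab <- data.frame(
    FID = ind$family_id, IID = ind$id,
    PAT = ifelse(is.na(ind$father_id), "0", ind$father_id),
    MAT = ifelse(is.na(ind$mother_id), "0", ind$mother_id),
    SEX = c(male = "1", female = "2", unknown = "0")[ind$sex],
    PHENO = ifelse(aff, "2", ifelse(ind$phenotype == "unaffected", "1", "0")),
    SUBTYPE = ifelse(aff, ind$phenotype, "."),
    SEQ = ifelse(ind$sequenced, "1", "0"))
  utils::write.table(tab, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  ind <- x$individuals
  fams <- family_ids(x)
  cat("cohort:", nrow(ind), "individuals;",
      length(fams), "families;",
      sum(ind$role == "sporadic_case"), "sporadic cases;",
      sum(ind$role == "control"), "controls\n")
  invisible(x)
}

#' Family ids of the multi-member families in a cohort
#' @param cohort a `cohort`.
#' @return character vector.
#' @export
family_ids <- function(cohort) {
  ind <- cohort$individuals
  unique(ind$family_id[ind$role == "family"])
}

#' Extract one family as a `family_ped`
#'
#' @param cohort a `cohort`.
#' @param family_id family id.
#' @return a `family_ped`: the family's individual table in topological
#'   order (founders first).
#' @export
get_family <- function(cohort, family_id) {
  ind <- cohort$individuals[cohort$individuals$family_id == family_id, ]
  if (nrow(ind) == 0) stop("no such family: ", family_id)
  as_family_ped(ind)
}

#' Coerce an individual table to a `family_ped`
#' @param ind individual table (one family).
#' @return `family_ped` object.
#' @export
as_family_ped <- function(ind) {
  if (inherits(ind, "family_ped")) return(ind)
  ind <- as.data.frame(ind)
  ord <- ped_topological_order(ind)
  out <- ind[match(ord, ind$id), ]
  rownames(out) <- NULL
  class(out) <- c("family_ped", "data.frame")
  out
}

#' Sequenced affected members of a family for a phenotype
#' @inheritParams pheno_matches
#' @param family a `family_ped`.
#' @return character vector of ids.
#' @export
affected_members <- function(family, phenotype = "IBD",
                             include_ibdu_in_cd = FALSE) {
  family$id[family$sequenced &
              pheno_matches(family$phenotype, phenotype, include_ibdu_in_cd)]
}
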