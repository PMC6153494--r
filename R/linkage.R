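#' Interpolate a genetic-map position
#'
#' Linear interpolation of centimorgan position between flanking map
#' anchors; positions outside the anchored range take the nearest
#' anchor's value (flat extrapolation).
#'
#' @param bp base-pair position(s).
#' @param map data.frame with columns `chrom`, `bp`, `cM` (anchors;
#'   `cM` non-decreasing in `bp` within a chromosome).
#' @param chrom chromosome to interpolate on.
#' @return cM position(s).
#' @export
interpolate_cm <- function(bp, map, chrom) {
  anchors <- map[map$chrom == chrom, ]
  if (nrow(anchors) == 0) stop("no map anchors for chromosome ", chrom)
  anchors <- anchors[order(anchors$bp), ]
  stats::approx(anchors$bp, anchors$cM, xout = bp, rule = 2, ties = "ordered")$y
}

#' Greedy windowed LD pruning
#'
#' PLINK-style `--indep-pairwise` pruning: within sliding windows of
#' `window` SNPs advanced by `step`, pairs with squared correlation above
#' `r2_max` lose the lower-MAF member. Monomorphic SNPs (undefined r2)
#' are dropped and reported.
#'
#' @param geno samples x SNPs dosage matrix, SNPs ordered by position.
#' @param window window size in SNPs (default 50).
#' @param step step size in SNPs (default 5).
#' @param r2_max r-squared threshold (default 0.2).
#' @return list with `kept` (SNP column names retained) and
#'   `monomorphic` (names dropped for zero variance).
#' @export
ld_prune <- function(geno, window = 50L, step = 5L, r2_max = 0.2) {
  geno <- as.matrix(geno)
  ids <- colnames(geno) %||% as.character(seq_len(ncol(geno)))
  colnames(geno) <- ids
  sdv <- apply(geno, 2, stats::sd, na.rm = TRUE)
  mono <- ids[is.na(sdv) | sdv == 0]
  keep <- !(ids %in% mono)
  maf <- vapply(seq_len(ncol(geno)), function(j) {
    af <- mean(geno[, j], na.rm = TRUE) / 2
    min(af, 1 - af)
  }, 0)
  start <- 1L
  repeat {
    idx <- which(keep)
    idx <- idx[idx >= start & idx < start + window]
    if (length(idx) > 1) {
      r2 <- suppressWarnings(
        stats::cor(geno[, idx, drop = FALSE],
                   use = "pairwise.complete.obs")^2)
      repeat {
        r2[is.na(r2)] <- 0
        diag(r2) <- 0
        mx <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        if (r2[mx[1], mx[2]] <= r2_max) break
        drop_local <- if (maf[idx[mx[1]]] <= maf[idx[mx[2]]]) mx[1] else mx[2]
        keep[idx[drop_local]] <- FALSE
        r2[drop_local, ] <- 0
        r2[, drop_local] <- 0
      }
    }
    if (start + window > ncol(geno)) break
    start <- start + step
  }
  list(kept = ids[keep], monomorphic = mono)
}

#' Build a sparse linkage SNP map
#'
#' Partitions each chromosome into fixed windows of `window_cm`
#' centimorgans anchored at the chromosome's first SNP and keeps, per
#' occupied window, the SNP with maximum heterozygosity `2 af (1 - af)`;
#' ties go to the lowest-MAF SNP, then to the smallest genomic position.
#' Deterministic under permutation of input order.
#'
#' @param snps data.frame with columns `key`, `chrom`, `cM`, `af` (and
#'   optionally `bp` for the final tie-break; `cM` order used otherwise).
#' @param window_cm window width in cM (default 0.3).
#' @return the retained subset of `snps`, ordered by chromosome and cM.
#' @export
build_linkage_map <- function(snps, window_cm = 0.3) {
  stopifnot(all(c("key", "chrom", "cM", "af") %in% names(snps)))
  snps <- as.data.frame(snps)
  snps$heterozygosity <- 2 * snps$af * (1 - snps$af)
  snps$maf <- pmin(snps$af, 1 - snps$af)
  bp <- if ("bp" %in% names(snps)) snps$bp else snps$cM
  out <- list()
  for (chrom in unique(snps$chrom)) {
    s <- snps[snps$chrom == chrom, ]
    o <- order(s$cM, bp[snps$chrom == chrom])
    s <- s[o, ]
    win <- floor((s$cM - s$cM[1]) / window_cm)
    for (w in unique(win)) {
      cand <- s[win == w, ]
      cand <- cand[order(-cand$heterozygosity, cand$maf, cand$cM, cand$key), ]
      out[[length(out) + 1]] <- cand[1, ]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Trim a pedigree to linkage-informative individuals
#'
#' Retains the sequenced individuals affected for the target phenotype
#' plus the minimal set of ancestors connecting them; a family is
#' informative when at least two affecteds remain.
#'
#' @param family a `family_ped`.
#' @param phenotype `"IBD"` or `"CD"`.
#' @return list with `family` (trimmed `family_ped`, possibly empty
#'   data.frame), `informative` (logical), `n_affected`.
#' @export
trim_pedigree <- function(family, phenotype = c("IBD", "CD")) {
  phenotype <- match.arg(phenotype)
  fam <- as_family_ped(family)
  aff <- affected_members(fam, phenotype)
  if (length(aff) < 2)
    return(list(family = fam[0, ], informative = FALSE,
                n_affected = length(aff)))
  # ancestors of each affected
  keep <- character(0)
  for (a in aff) {
    frontier <- a
    while (length(frontier) > 0) {
      keep <- union(keep, frontier)
      rows <- fam[match(frontier, fam$id), ]
      frontier <- setdiff(stats::na.omit(c(rows$father_id, rows$mother_id)),
                          keep)
    }
  }
  trimmed <- fam[fam$id %in% keep, ]
  # spouses needed so every retained non-founder still has two parents
  # are already ancestors of some affected; re-validate structure
  trimmed <- as_family_ped(trimmed)
  list(family = trimmed, informative = TRUE, n_affected = length(aff))
}

#' Select linkage loci from a LOD curve
#'
#' Maximal contiguous runs of map positions with LOD >= `threshold`,
#' each annotated with its peak LOD and bp extent.
#'
#' @param lod_curve data.frame with columns `chrom`, `bp`, `cM`, `lod`
#'   ordered along the map.
#' @param threshold LOD threshold (default 1.5, suggestive linkage).
#' @return data.frame of loci: `chrom`, `start_bp`, `end_bp`, `start_cm`,
#'   `end_cm`, `peak_lod`.
#' @export
select_loci <- function(lod_curve, threshold = 1.5) {
  out <- list()
  for (chrom in unique(lod_curve$chrom)) {
    s <- lod_curve[lod_curve$chrom == chrom, ]
    s <- s[order(s$bp), ]
    above <- s$lod >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      seg <- s[starts[i]:ends[i], ]
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start_bp = min(seg$bp), end_bp = max(seg$bp),
        start_cm = min(seg$cM), end_cm = max(seg$cM),
        peak_lod = max(seg$lod), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), start_cm = numeric(0),
                      end_cm = numeric(0), peak_lod = numeric(0)))
  do.call(rbind, out)
}

#' Families contributing to a linkage locus
#'
#' A family contributes when its mean per-family LOD across the locus is
#' strictly positive. Families with no values at the locus are excluded
#' with a warning.
#'
#' @param per_family_lod data.frame with `family_id`, `chrom`, `bp` (or
#'   `start_bp`/`end_bp` interval rows), `lod`.
#' @param locus one row of [select_loci()] output.
#' @return character vector of contributing family ids.
#' @export
contributing_families <- function(per_family_lod, locus) {
  tab <- per_family_lod
  if (!"bp" %in% names(tab) && all(c("start_bp", "end_bp") %in% names(tab))) {
    tab$bp <- (tab$start_bp + tab$end_bp) / 2
    at <- tab$chrom == locus$chrom &
      tab$end_bp >= locus$start_bp & tab$start_bp <= locus$end_bp
  } else {
    at <- tab$chrom == locus$chrom & tab$bp >= locus$start_bp &
      tab$bp <= locus$end_bp
  }
  fams <- unique(tab$family_id)
  means <- vapply(fams, function(f) {
    x <- tab$lod[at & tab$family_id == f]
    if (length(x) == 0) NA_real_ else mean(x)
  }, 0)
  if (anyNA(means))
    warning("families with no LOD values at locus excluded: ",
            paste(fams[is.na(means)], collapse = ", "))
  sort(fams[!is.na(means) & means > 0])
}

#' Shared rare damaging variants under linkage loci
#'
#' The multi-family prioritization rule: keep variants that are rare
#' (control AF < `af_max`), damaging, lie in a gene overlapping a
#' selected locus, and are carried by at least `min_carriers` affected
#' members in each of at least `min_families` families contributing to
#' that locus.
#'
#' @param vs annotated, oriented, QC-passed `variant_set`; `variants`
#'   must carry `gene`, `consequence`, `carol`, `cadd` and panel AFs.
#' @param loci [select_loci()] output.
#' @param cohort the family `cohort`.
#' @param per_family_lod per-family LOD table (see
#'   [contributing_families()]).
#' @param genes gene interval table: `gene`, `chrom`, `start`, `end`.
#' @param phenotype `"IBD"` or `"CD"`.
#' @param af_max control-AF ceiling (default 0.05).
#' @param min_carriers minimum affected carriers per family (default 2).
#' @param min_families minimum contributing families (default 2).
#' @return data.frame of prioritized variants with `n_families` and the
#'   contributing family ids.
#' @export
linkage_shared_variants <- function(vs, loci, cohort, per_family_lod, genes,
                                    phenotype = c("IBD", "CD"),
                                    af_max = 0.05, min_carriers = 2L,
                                    min_families = 2L) {
  phenotype <- match.arg(phenotype)
  v <- vs$variants
  caf <- control_af(v$af_aj, v$af_nfe, v$af_paj,
                    if ("af_aj_wgs" %in% names(v)) v$af_aj_wgs else NA,
                    context = "filtering")
  damaging <- is_damaging(v$consequence, v$carol, v$cadd)
  rare <- !caf$af_unknown & caf$control_af < af_max
  out <- list()
  for (li in seq_len(nrow(loci))) {
    locus <- loci[li, ]
    gsel <- genes$gene[genes$chrom == locus$chrom &
                         genes$end >= locus$start_bp &
                         genes$start <= locus$end_bp]
    contrib <- contributing_families(per_family_lod, locus)
    if (length(contrib) == 0) next
    cand <- which(rare & damaging & v$gene %in% gsel)
    for (j in cand) {
      fam_hits <- character(0)
      for (f in contrib) {
        fam <- get_family(cohort, f)
        aff <- affected_members(fam, phenotype)
        aff <- intersect(aff, rownames(vs$geno))
        if (length(aff) == 0) next
        n_car <- sum(vs$geno[aff, j] >= 1, na.rm = TRUE)
        if (n_car >= min_carriers) fam_hits <- c(fam_hits, f)
      }
      if (length(fam_hits) >= min_families)
        out[[length(out) + 1]] <- data.frame(
          key = v$key[j], gene = v$gene[j],
          consequence = v$consequence[j],
          control_af = caf$control_af[j],
          locus_chrom = locus$chrom, peak_lod = locus$peak_lod,
          n_families = length(fam_hits),
          families = paste(fam_hits, collapse = ","),
          phenotype = phenotype, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(key = character(0), gene = character(0),
                      consequence = character(0), control_af = numeric(0),
                      locus_chrom = character(0), peak_lod = numeric(0),
                      n_families = integer(0), families = character(0),
                      phenotype = character(0)))
  res <- do.call(rbind, out)
  res[!duplicated(res$key), , drop = FALSE]
}
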