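#' Quality-control thresholds
#'
#' Defaults follow standard exome-cohort practice for GATK-called data:
#' genotypes need GQ >= 30, alternate read depth >= 3 for het/hom-alt
#' calls, and heterozygote allele balance consistent with 1:1 (chi-squared
#' p >= 0.001); variants need call rate >= 0.75, Hardy-Weinberg p >=
#' 5e-8, and a VQSR truth tranche <= 99.5 (SNPs) / 99.0 (indels).
#'
#' @param min_gq minimum genotype quality.
#' @param min_alt_depth minimum alternate read depth for carriers.
#' @param ab_p_min minimum allele-balance chi-squared p for hets.
#' @param min_call_rate minimum per-variant call rate.
#' @param hwe_p_min minimum Hardy-Weinberg chi-squared p.
#' @param max_tranche_snp,max_tranche_indel maximum VQSR tranche percent.
#' @param missing_quality how to treat genotypes whose quality fields are
#'   missing: `"pass"` (keep, flagged unevaluable) or `"fail"`.
#' @return list of thresholds, class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_gq = 30L, min_alt_depth = 3L,
                          ab_p_min = 0.001, min_call_rate = 0.75,
                          hwe_p_min = 5e-8, max_tranche_snp = 99.5,
                          max_tranche_indel = 99.0,
                          missing_quality = c("pass", "fail")) {
  stopifnot(min_gq >= 0, min_alt_depth >= 0,
            ab_p_min >= 0, ab_p_min <= 1,
            min_call_rate >= 0, min_call_rate <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1,
            max_tranche_snp > 0, max_tranche_indel > 0)
  structure(list(min_gq = min_gq, min_alt_depth = min_alt_depth,
                 ab_p_min = ab_p_min, min_call_rate = min_call_rate,
                 hwe_p_min = hwe_p_min, max_tranche_snp = max_tranche_snp,
                 max_tranche_indel = max_tranche_indel,
                 missing_quality = match.arg(missing_quality)),
            class = "qc_thresholds")
}

#' Heterozygote allele-balance test
#'
#' Chi-squared test (with continuity correction) of (ref, alt) read
#' depths against the 1:1 ratio expected for a true heterozygote.
#'
#' @param ad_ref,ad_alt read depths.
#' @return two-sided p-value.
#' @export
allele_balance_p <- function(ad_ref, ad_alt) {
  n <- ad_ref + ad_alt
  if (any(n == 0)) stop("zero total depth")
  # continuity-corrected chi-square against p = 0.5
  stat <- (pmax(abs(ad_ref - n / 2) - 0.5, 0))^2 / (n / 4)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Genotype-level quality control
#'
#' @param dosage genotype dosage (0/1/2) or `NA`.
#' @param gq genotype quality (or `NA`).
#' @param ad_ref,ad_alt allelic depths (or `NA`).
#' @param thresholds a [qc_thresholds()].
#' @return character: `"pass"`, or the failure reason
#'   (`"gq"`, `"depth"`, `"allele_balance"`, `"missing"`), or
#'   `"unevaluable"` when quality fields are absent and
#'   `missing_quality = "pass"`.
#' @export
genotype_qc <- function(dosage, gq, ad_ref, ad_alt,
                        thresholds = qc_thresholds()) {
  if (is.na(dosage)) return("missing")
  if (dosage == 0) {
    # hom-ref calls: only GQ is checked
    if (is.na(gq))
      return(if (thresholds$missing_quality == "pass") "unevaluable" else "gq")
    return(if (gq < thresholds$min_gq) "gq" else "pass")
  }
  if (is.na(gq) || is.na(ad_ref) || is.na(ad_alt))
    return(if (thresholds$missing_quality == "pass") "unevaluable"
           else "missing_quality")
  if (gq < thresholds$min_gq) return("gq")
  # allele balance is the more specific failure for skewed het calls
  if (dosage == 1 && ad_ref + ad_alt > 0 &&
      allele_balance_p(ad_ref, ad_alt) < thresholds$ab_p_min)
    return("allele_balance")
  if (ad_alt < thresholds$min_alt_depth) return("depth")
  "pass"
}

#' Apply genotype QC across a variant set
#'
#' Failing genotypes are set to missing so that downstream call-rate and
#' HWE checks see them as no-calls.
#'
#' @param vs a `variant_set`.
#' @param thresholds a [qc_thresholds()].
#' @return the variant set with failing genotypes masked; the per-call QC
#'   verdicts are attached as attribute `genotype_qc`.
#' @export
mask_failing_genotypes <- function(vs, thresholds = qc_thresholds()) {
  verdicts <- vs$geno
  mode(verdicts) <- "character"
  for (j in seq_len(ncol(vs$geno))) {
    for (i in seq_len(nrow(vs$geno))) {
      verdicts[i, j] <- genotype_qc(vs$geno[i, j], vs$gq[i, j],
                                    vs$ad_ref[i, j], vs$ad_alt[i, j],
                                    thresholds)
    }
  }
  fail <- !(verdicts %in% c("pass", "unevaluable", "missing"))
  vs$geno[fail] <- NA_integer_
  attr(vs, "genotype_qc") <- verdicts
  vs
}

#' Hardy-Weinberg chi-squared test
#'
#' One-degree-of-freedom chi-squared test of observed genotype counts
#' against Hardy-Weinberg expectations at the sample allele frequency.
#' Monomorphic sites return p = 1.
#'
#' @param n_rr,n_ra,n_aa counts of hom-ref, het, hom-alt genotypes.
#' @return p-value.
#' @export
hwe_chi2 <- function(n_rr, n_ra, n_aa) {
  n <- n_rr + n_ra + n_aa
  if (n <= 0) stop("all-zero genotype counts")
  p <- (2 * n_aa + n_ra) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((c(n_rr, n_ra, n_aa) - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Variant-level quality control
#'
#' Expects genotype QC already applied (failed calls masked missing).
#'
#' @param vs a `variant_set`.
#' @param thresholds a [qc_thresholds()].
#' @return data.frame with `key`, `call_rate`, `hwe_p`, `pass` and a
#'   comma-separated `reasons` column (`call_rate`, `hwe`, `tranche`).
#' @export
variant_qc <- function(vs, thresholds = qc_thresholds()) {
  v <- vs$variants
  out <- data.frame(key = v$key, call_rate = NA_real_, hwe_p = NA_real_,
                    pass = NA, reasons = "", stringsAsFactors = FALSE)
  for (j in seq_len(nrow(v))) {
    g <- vs$geno[, j]
    cr <- mean(!is.na(g))
    hp <- if (all(is.na(g))) 0 else
      hwe_chi2(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
               sum(g == 2, na.rm = TRUE))
    reasons <- character(0)
    if (cr < thresholds$min_call_rate) reasons <- c(reasons, "call_rate")
    if (hp < thresholds$hwe_p_min) reasons <- c(reasons, "hwe")
    max_tranche <- if (isTRUE(v$is_snp[j])) thresholds$max_tranche_snp
      else thresholds$max_tranche_indel
    if (!is.na(v$vqsr_tranche[j]) && v$vqsr_tranche[j] > max_tranche)
      reasons <- c(reasons, "tranche")
    out$call_rate[j] <- cr
    out$hwe_p[j] <- hp
    out$pass[j] <- length(reasons) == 0
    out$reasons[j] <- paste(reasons, collapse = ",")
  }
  out
}

#' Infer genetic sex from X-chromosome homozygosity
#'
#' Males are hemizygous on the non-pseudoautosomal X, so their
#' homozygosity rate at common X variants approaches 1; females sit near
#' the autosomal-like rate. Calls between the two thresholds are
#' ambiguous.
#'
#' @param x_hom_rate homozygosity rate over common non-PAR X variants.
#' @param n_variants number of variants the rate was computed over.
#' @param female_max,male_min the two thresholds (defaults 0.8, 0.9).
#' @param min_variants minimum variant count required.
#' @return `"male"`, `"female"` or `"ambiguous"`.
#' @export
infer_sex <- function(x_hom_rate, n_variants = Inf, female_max = 0.8,
                      male_min = 0.9, min_variants = 100L) {
  stopifnot(female_max < male_min)
  if (n_variants < min_variants)
    stop("too few X variants (", n_variants, " < ", min_variants, ")")
  if (x_hom_rate >= male_min) "male"
  else if (x_hom_rate <= female_max) "female"
  else "ambiguous"
}

#' Map a kinship coefficient to a relationship class
#'
#' Uses the standard KING-style cut points: phi > 0.354 duplicate/MZ,
#' (0.177, 0.354] first degree, (0.0884, 0.177] second, (0.0442, 0.0884]
#' third, otherwise unrelated. Bins are lower-inclusive / upper-exclusive
#' going downward so every coefficient maps to exactly one class.
#'
#' @param phi kinship coefficient(s), in \[-0.5, 0.5\].
#' @return character vector: `duplicate`, `first`, `second`, `third`,
#'   `unrelated`.
#' @export
classify_kinship <- function(phi) {
  stopifnot(all(phi >= -0.5 & phi <= 0.5))
  cut_points <- c(0.354, 0.177, 0.0884, 0.0442)
  out <- rep("unrelated", length(phi))
  out[phi >= cut_points[4]] <- "third"
  out[phi >= cut_points[3]] <- "second"
  out[phi >= cut_points[2]] <- "first"
  out[phi > cut_points[1]] <- "duplicate"
  out
}

#' Expected kinship matrix of a pedigree
#'
#' Recursive pedigree kinship: founders are mutually unrelated and
#' non-inbred; phi(i,i) = 0.5 (1 + phi(father, mother)); for a
#' non-founder i and any j that is not a descendant of i,
#' phi(i,j) = 0.5 (phi(father_i, j) + phi(mother_i, j)).
#'
#' @param family a `family_ped` (or family individual table).
#' @return symmetric kinship matrix with individual ids as dimnames.
#' @export
pedigree_kinship <- function(family) {
  fam <- as_family_ped(family)   # topological order; errors on cycles
  n <- nrow(fam)
  phi <- matrix(0, n, n, dimnames = list(fam$id, fam$id))
  fa <- match(fam$father_id, fam$id)
  mo <- match(fam$mother_id, fam$id)
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 * (1 + phi[fa[i], mo[i]])
      for (j in seq_len(i - 1)) {
        phi[i, j] <- phi[j, i] <- 0.5 * (phi[fa[i], j] + phi[mo[i], j])
      }
    }
  }
  phi
}

#' Fit a Gaussian ancestry ellipsoid in PC space
#'
#' Iteratively trims multivariate outliers (Mahalanobis d-squared above
#' the `1 - outlier_q` chi-squared quantile) then fits mean and
#' covariance; membership is defined by the chi-squared quantile of the
#' requested coverage on `n_pcs` degrees of freedom.
#'
#' @param points n x k matrix of PC coordinates (k >= n_pcs).
#' @param n_pcs number of leading PCs used (default 5).
#' @param coverage ellipsoid coverage (default 0.90).
#' @param outlier_q tail probability for outlier trimming (default 1e-3).
#' @param max_iter trimming iteration cap.
#' @return list of class `ancestry_model` with `mean`, `covariance`,
#'   `n_pcs`, `coverage`, `d2_threshold`, `n_used`, `outliers` (row
#'   indices trimmed).
#' @export
fit_ancestry_ellipsoid <- function(points, n_pcs = 5L, coverage = 0.90,
                                   outlier_q = 1e-3, max_iter = 20L) {
  points <- as.matrix(points)
  if (ncol(points) < n_pcs) stop("fewer columns than n_pcs")
  x <- points[, seq_len(n_pcs), drop = FALSE]
  if (nrow(x) <= n_pcs) stop("need more points than PCs")
  keep <- rep(TRUE, nrow(x))
  trim_d2 <- stats::qchisq(1 - outlier_q, df = n_pcs)
  for (it in seq_len(max_iter)) {
    mu <- colMeans(x[keep, , drop = FALSE])
    sigma <- stats::cov(x[keep, , drop = FALSE])
    if (any(!is.finite(sigma)) || det(sigma) <= 0)
      stop("singular covariance; reduce n_pcs")
    d2 <- stats::mahalanobis(x, mu, sigma)
    new_keep <- d2 <= trim_d2
    if (identical(new_keep, keep)) break
    keep <- new_keep
    if (sum(keep) <= n_pcs) stop("outlier trimming removed too many points")
  }
  structure(list(mean = mu, covariance = sigma, n_pcs = n_pcs,
                 coverage = coverage,
                 d2_threshold = stats::qchisq(coverage, df = n_pcs),
                 n_used = sum(keep), outliers = which(!keep)),
            class = "ancestry_model")
}

#' Ellipsoid membership
#' @param model an `ancestry_model`.
#' @param points matrix of PC coordinates.
#' @return logical vector: inside the coverage ellipsoid?
#' @export
in_ellipsoid <- function(model, points) {
  x <- as.matrix(points)[, seq_len(model$n_pcs), drop = FALSE]
  stats::mahalanobis(x, model$mean, model$covariance) <= model$d2_threshold
}

#' Rank candidate controls by ancestry proximity
#'
#' Orders candidates by Mahalanobis distance to the fitted ancestry
#' centre and returns the `k` nearest (ties broken by id for
#' determinism).
#'
#' @param model an `ancestry_model`.
#' @param candidates matrix of PC coordinates with rownames = ids.
#' @param k number of proximal controls to select (default 500).
#' @return character vector of ids, nearest first.
#' @export
rank_proximal_controls <- function(model, candidates, k = 500L) {
  x <- as.matrix(candidates)[, seq_len(model$n_pcs), drop = FALSE]
  ids <- rownames(candidates) %||% as.character(seq_len(nrow(x)))
  d2 <- stats::mahalanobis(x, model$mean, model$covariance)
  if (k > length(ids)) {
    warning("k = ", k, " exceeds ", length(ids), " candidates; returning all")
    k <- length(ids)
  }
  ids[order(d2, ids)][seq_len(k)]
}

#' Principal components of a genotype matrix with projection
#'
#' Centred (optionally scaled) eigendecomposition of common LD-pruned
#' genotypes; held-out samples are projected with the training loadings.
#'
#' @param geno samples x SNPs dosage matrix (training samples).
#' @param n_pcs number of PCs to retain.
#' @param scale. scale columns to unit variance? Default `TRUE`.
#' @return list with `scores` (training PCs), `project(newgeno)` closure,
#'   `loadings`, `center`, `scale`.
#' @export
pca_fit <- function(geno, n_pcs = 5L, scale. = TRUE) {
  geno <- as.matrix(geno)
  # mean-impute missings per SNP before decomposition
  for (j in seq_len(ncol(geno))) {
    m <- is.na(geno[, j])
    if (any(m)) geno[m, j] <- mean(geno[, j], na.rm = TRUE)
  }
  sdv <- apply(geno, 2, stats::sd)
  keep <- sdv > 0
  pc <- stats::prcomp(geno[, keep, drop = FALSE], center = TRUE,
                      scale. = scale.)
  n_pcs <- min(n_pcs, ncol(pc$x))
  center <- pc$center; scl <- pc$scale; rot <- pc$rotation[, seq_len(n_pcs)]
  project <- function(newgeno) {
    ng <- as.matrix(newgeno)[, keep, drop = FALSE]
    for (j in seq_len(ncol(ng))) {
      m <- is.na(ng[, j])
      if (any(m)) ng[m, j] <- center[j]
    }
    ng <- sweep(ng, 2, center)
    if (!isFALSE(scl)) ng <- sweep(ng, 2, scl, "/")
    ng %*% rot
  }
  list(scores = pc$x[, seq_len(n_pcs), drop = FALSE], project = project,
       loadings = rot, center = center, scale = scl)
}

#' Pairwise genotype concordance
#'
#' Fraction of equal calls among sites where both vectors are observed.
#'
#' @param a,b equal-length genotype dosage vectors (`NA` = missing).
#' @return concordance fraction.
#' @export
genotype_concordance <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no co-observed sites")
  mean(a[ok] == b[ok])
}
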