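#' Canonical variant key
#'
#' Variants are identified as `chrom_pos_ref_alt` with a 1-based build-37
#' position and upper-case alleles, e.g. `16_50763778_G_GC`.
#'
#' @param chrom chromosome label (number, `X`, ...).
#' @param pos 1-based position.
#' @param ref,alt reference / alternate allele strings.
#' @return character key vector.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (any(!is.finite(pos)) || any(pos < 1)) stop("position must be >= 1")
  if (any(nchar(ref) == 0) || any(nchar(alt) == 0)) stop("empty allele string")
  if (any(ref == alt)) stop("ref and alt alleles identical")
  if (any(grepl("[^ACGTN*]", c(ref, alt)))) stop("non-nucleotide allele characters")
  paste(chrom, format(pos, scientific = FALSE, trim = TRUE), ref, alt, sep = "_")
}

#' Variant set container
#'
#' Bundles a variant metadata table with per-sample genotype matrices:
#' `geno` (dosage of the alternate allele, `NA` = missing), `gq`, `ad_ref`
#' and `ad_alt` (all samples x variants, column names = variant keys).
#'
#' @param variants data.frame with at least `key`, `chrom`, `pos`, `ref`,
#'   `alt`; optionally annotation columns (`gene`, `consequence`, `carol`,
#'   `cadd`, `af_aj`, `af_nfe`, `af_paj`, `af_aj_wgs`, `vqsr_tranche`,
#'   `is_snp`, ...).
#' @param geno,gq,ad_ref,ad_alt samples x variants matrices (gq/ad may be
#'   `NULL` when unavailable; they are then all-`NA` and records are
#'   flagged `gq_missing`/`ad_missing`).
#' @return object of class `variant_set`.
#' @export
variant_set <- function(variants, geno, gq = NULL, ad_ref = NULL,
                        ad_alt = NULL) {
  variants <- as.data.frame(variants)
  stopifnot(all(c("key", "chrom", "pos", "ref", "alt") %in% names(variants)))
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(variants))
    stop("geno has ", ncol(geno), " columns but ", nrow(variants), " variants")
  colnames(geno) <- variants$key
  blank <- function(m, what) {
    if (is.null(m)) {
      m <- matrix(NA_integer_, nrow(geno), ncol(geno),
                  dimnames = dimnames(geno))
      attr(m, "all_missing") <- TRUE
    } else {
      m <- as.matrix(m)
      stopifnot(identical(dim(m), dim(geno)))
      dimnames(m) <- dimnames(geno)
    }
    m
  }
  structure(list(variants = variants, geno = geno,
                 gq = blank(gq), ad_ref = blank(ad_ref),
                 ad_alt = blank(ad_alt)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "variants x",
      nrow(x$geno), "samples\n")
  invisible(x)
}

#' Samples of a variant set
#' @param vs a `variant_set`.
#' @return character vector of sample ids.
#' @export
vs_samples <- function(vs) rownames(vs$geno)

#' Subset a variant set by variant keys and/or samples
#' @param vs a `variant_set`.
#' @param keys variant keys to retain (default all).
#' @param samples sample ids to retain (default all).
#' @return a `variant_set`.
#' @export
vs_subset <- function(vs, keys = NULL, samples = NULL) {
  vi <- if (is.null(keys)) seq_len(nrow(vs$variants)) else {
    idx <- match(keys, vs$variants$key)
    if (anyNA(idx)) stop("unknown variant keys: ",
                         paste(keys[is.na(idx)], collapse = ", "))
    idx
  }
  si <- if (is.null(samples)) seq_len(nrow(vs$geno)) else {
    idx <- match(samples, rownames(vs$geno))
    if (anyNA(idx)) stop("unknown samples: ",
                         paste(samples[is.na(idx)], collapse = ", "))
    idx
  }
  variant_set(vs$variants[vi, , drop = FALSE],
              vs$geno[si, vi, drop = FALSE],
              vs$gq[si, vi, drop = FALSE],
              vs$ad_ref[si, vi, drop = FALSE],
              vs$ad_alt[si, vi, drop = FALSE])
}

# parse one GT string vector against a given alt-allele index (1-based
# among ALTs); returns dosage of that alt with NA for missing
.gt_dosage <- function(gt, alt_index) {
  gt <- sub(":.*", "", gt)
  a <- strsplit(gt, "[/|]")
  vapply(a, function(al) {
    if (length(al) == 0 || any(al == ".")) return(NA_integer_)
    sum(al == as.character(alt_index))
  }, 0L)
}

#' Read a multi-sample VCF into a variant set
#'
#' Parses a VCF v4.2 text file with `GT` (and optionally `GQ`, `AD`)
#' FORMAT fields. Multiallelic sites are split into one record per
#' alternate allele; `AD` is collapsed to (ref, this-alt). `VQSLOD`-style
#' tranche labels are read from an INFO key (default `TRANCHE`).
#'
#' Uses `VariantAnnotation::readVcf()` when available (the default); the
#' parsed object is converted to the package's matrix container.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param tranche_info INFO field holding the VQSR truth-tranche percent.
#' @return a [variant_set()]; records missing GQ or AD are flagged in
#'   `variants$gq_missing` / `variants$ad_missing`.
#' @export
read_vcf <- function(path, tranche_info = "TRANCHE") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  fx <- VariantAnnotation::fixed(vcf)
  alt_list <- as.list(fx$ALT)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(fx$REF)
  gt <- VariantAnnotation::geno(vcf)$GT   # variants x samples (character)
  if (is.null(gt)) stop("VCF has no GT FORMAT field")
  has_gq <- "GQ" %in% names(VariantAnnotation::geno(vcf))
  has_ad <- "AD" %in% names(VariantAnnotation::geno(vcf))
  if (!has_gq) warning("VCF has no GQ field; genotype QC on GQ unevaluable")
  if (!has_ad) warning("VCF has no AD field; allele-balance QC unevaluable")
  gq <- if (has_gq) VariantAnnotation::geno(vcf)$GQ
  ad <- if (has_ad) VariantAnnotation::geno(vcf)$AD
  info <- VariantAnnotation::info(vcf)
  tranche <- if (tranche_info %in% names(info))
    as.numeric(info[[tranche_info]]) else rep(NA_real_, length(rr))

  samples <- colnames(gt)
  out_meta <- list(); out_geno <- list(); out_gq <- list()
  out_adr <- list(); out_ada <- list()
  k <- 0
  for (i in seq_along(alt_list)) {
    alts <- as.character(alt_list[[i]])
    for (j in seq_along(alts)) {
      alt <- alts[j]
      if (alt %in% c("*", ".") || alt == "") next
      k <- k + 1
      out_meta[[k]] <- data.frame(
        key = variant_key(chrom[i], pos[i], ref[i], alt),
        chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alt,
        vqsr_tranche = tranche[i],
        is_snp = nchar(ref[i]) == 1 && nchar(alt) == 1,
        n_alt_alleles = length(alts),
        stringsAsFactors = FALSE)
      out_geno[[k]] <- .gt_dosage(gt[i, ], j)
      out_gq[[k]] <- if (has_gq) suppressWarnings(as.integer(gq[i, ])) else
        rep(NA_integer_, length(samples))
      if (has_ad) {
        adi <- ad[i, ]
        out_adr[[k]] <- vapply(adi, function(x)
          if (length(x) >= 1) as.integer(x[1]) else NA_integer_, 0L)
        out_ada[[k]] <- vapply(adi, function(x)
          if (length(x) >= j + 1) as.integer(x[j + 1]) else NA_integer_, 0L)
      } else {
        out_adr[[k]] <- out_ada[[k]] <- rep(NA_integer_, length(samples))
      }
    }
  }
  meta <- do.call(rbind, out_meta)
  meta$gq_missing <- !has_gq
  meta$ad_missing <- !has_ad
  bind <- function(l) {
    m <- do.call(cbind, l)
    rownames(m) <- samples
    m
  }
  variant_set(meta, bind(out_geno), bind(out_gq), bind(out_adr),
              bind(out_ada))
}

#' Write a variant set to a minimal VCF v4.2 file
#'
#' Emits biallelic records with GT, GQ and AD per sample and the VQSR
#' tranche as an INFO field, suitable for round-tripping via [read_vcf()].
#'
#' @param vs a `variant_set`.
#' @param path output path.
#' @export
write_vcf <- function(vs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=TRANCHE,Number=1,Type=Float,Description=\"VQSR truth tranche percent\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(vs$geno)), collapse = "\t")), con)
  v <- vs$variants
  gt_str <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(v))) {
    g <- vs$geno[, i]
    gs <- ifelse(is.na(g), "./.", gt_str[g + 1])
    gqs <- ifelse(is.na(vs$gq[, i]), ".", as.character(vs$gq[, i]))
    ads <- ifelse(is.na(vs$ad_ref[, i]) | is.na(vs$ad_alt[, i]), ".",
                  paste0(vs$ad_ref[, i], ",", vs$ad_alt[, i]))
    fields <- paste(gs, gqs, ads, sep = ":")
    info <- if (is.na(v$vqsr_tranche[i])) "." else
      paste0("TRANCHE=", format(v$vqsr_tranche[i]))
    writeLines(paste(c(v$chrom[i], v$pos[i], v$key[i], v$ref[i], v$alt[i],
                       ".", "PASS", info, "GT:GQ:AD", fields),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a variant annotation table and attach it to a variant set
#'
#' The annotation TSV carries columns `key`, `gene`, `consequence`,
#' `effect_hgvs`, `carol`, `cadd`, `af_aj`, `af_nfe`, `af_paj`,
#' `af_aj_wgs`. Missing AFs are `NA` ("absent", never zero).
#'
#' @param vs a `variant_set`.
#' @param path annotation TSV path.
#' @return the variant set with annotation columns merged on `key`.
#' @export
attach_annotations <- function(vs, path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("key" %in% names(ann))
  keep <- setdiff(names(ann), setdiff(names(vs$variants), "key"))
  vs$variants <- merge(vs$variants, ann[, keep, drop = FALSE],
                       by = "key", all.x = TRUE, sort = FALSE)
  # merge() may reorder; restore genotype column order
  vs$variants <- vs$variants[match(colnames(vs$geno), vs$variants$key), ]
  rownames(vs$variants) <- NULL
  vs
}

#' Write a tab-separated results report
#'
#' Mirrors the layout of the study's prioritized-variant tables: one row
#' per variant with annotation, control AF, family counts and (when
#' present) replication statistics. Reading the file back with
#' [read_report()] reproduces the data.frame.
#'
#' @param results data.frame of results (any downstream stage).
#' @param path output path.
#' @export
write_report <- function(results, path) {
  utils::write.table(results, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_report
#' @return `read_report`: the report as a data.frame.
#' @export
read_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
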