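#' Orient a variant set to the minor allele
#'
#' When the reference genome carries the minor allele (deciding panel AF
#' > 0.5), dosages are flipped (0 <-> 2) and every panel AF becomes
#' 1 - AF; the record is marked `flipped`. The deciding AF is the first
#' available of the proximal-AJ, gnomAD-AJ and gnomAD-NFE panels.
#' Records with no panel AF at all are left unchanged and flagged
#' `unoriented`.
#'
#' @param vs a `variant_set` with annotation columns `af_aj`, `af_nfe`,
#'   `af_paj` (and optionally `af_aj_wgs`).
#' @return the oriented variant set, with logical columns `flipped` and
#'   `unoriented` added.
#' @export
orient_to_minor_allele <- function(vs) {
  v <- vs$variants
  af_cols <- intersect(c("af_aj", "af_nfe", "af_paj", "af_aj_wgs"), names(v))
  if (length(af_cols) == 0) stop("no panel AF columns present")
  deciding_order <- intersect(c("af_paj", "af_aj", "af_nfe"), af_cols)
  deciding <- rep(NA_real_, nrow(v))
  for (col in deciding_order) deciding[is.na(deciding)] <- v[[col]][is.na(deciding)]
  flip <- !is.na(deciding) & deciding > 0.5
  v$unoriented <- is.na(deciding)
  v$flipped <- flip
  for (col in af_cols) {
    af <- v[[col]]
    v[[col]] <- ifelse(flip & !is.na(af), 1 - af, af)
  }
  if (any(flip)) {
    vs$geno[, flip] <- 2L - vs$geno[, flip, drop = FALSE]
    # allelic depths swap roles under the flip
    tmp <- vs$ad_ref[, flip, drop = FALSE]
    vs$ad_ref[, flip] <- vs$ad_alt[, flip, drop = FALSE]
    vs$ad_alt[, flip] <- tmp
  }
  vs$variants <- v
  vs
}

#' Is a variant damaging?
#'
#' Frameshift, start-loss, stop-gain and splice acceptor/donor variants
#' are damaging unconditionally. A missense variant is damaging only when
#' CAROL calls it damaging and its CADD (PHRED) score is >= `cadd_min`.
#' Everything else — including missense with a missing CAROL call or CADD
#' score — is not.
#'
#' @param consequence consequence class (`frameshift`, `start_loss`,
#'   `stop_gain`, `splice_acceptor`, `splice_donor`, `missense`, other).
#' @param carol CAROL call: `damaging`, `benign` or `NA`.
#' @param cadd CADD PHRED score or `NA`.
#' @param cadd_min missense CADD threshold (default 20).
#' @return logical vector.
#' @export
is_damaging <- function(consequence, carol = NA, cadd = NA, cadd_min = 20) {
  high_impact <- c("frameshift", "start_loss", "stop_gain",
                   "splice_acceptor", "splice_donor")
  n <- length(consequence)
  carol <- rep_len(carol, n); cadd <- rep_len(cadd, n)
  out <- consequence %in% high_impact
  mis <- consequence == "missense"
  out[mis] <- !is.na(carol[mis]) & carol[mis] == "damaging" &
    !is.na(cadd[mis]) & cadd[mis] >= cadd_min
  out
}

#' Resolve the control allele frequency of a variant
#'
#' The control AF is the maximum over the available gnomAD-AJ, gnomAD-NFE
#' and proximal-AJ panel frequencies; missing panels are absent, not
#' zero. In the gene-dropping context, a missing gnomAD-AJ exome AF is
#' substituted by the gnomAD-AJ whole-genome AF before the maximum is
#' taken. When every source is missing the AF is 0 with `af_unknown`
#' set.
#'
#' @param af_aj,af_nfe,af_paj,af_aj_wgs panel AFs (`NA` = absent).
#' @param context `"filtering"` (default) or `"genedrop"`.
#' @return data.frame with `control_af` and logical `af_unknown`.
#' @export
control_af <- function(af_aj = NA, af_nfe = NA, af_paj = NA,
                       af_aj_wgs = NA, context = c("filtering", "genedrop")) {
  context <- match.arg(context)
  n <- max(length(af_aj), length(af_nfe), length(af_paj), length(af_aj_wgs))
  af_aj <- rep_len(af_aj, n); af_nfe <- rep_len(af_nfe, n)
  af_paj <- rep_len(af_paj, n); af_aj_wgs <- rep_len(af_aj_wgs, n)
  if (context == "genedrop")
    af_aj <- ifelse(is.na(af_aj), af_aj_wgs, af_aj)
  m <- cbind(af_aj, af_nfe, af_paj)
  af <- apply(m, 1, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  data.frame(control_af = ifelse(is.na(af), 0, af), af_unknown = is.na(af))
}

#' Classify an allele frequency into rarity tiers
#'
#' Tiers follow strict thresholds: `very_rare` (AF < 0.005), `rare`
#' (0.005 <= AF <= 0.05) and `common` (AF > 0.05); an AF of exactly 0.05
#' or 0.005 is `rare`.
#'
#' @param af allele frequency in \[0, 1\].
#' @return character vector: `very_rare`, `rare`, `common`.
#' @export
classify_af_tier <- function(af) {
  stopifnot(all(af >= 0 & af <= 1))
  ifelse(af < 0.005, "very_rare", ifelse(af > 0.05, "common", "rare"))
}
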