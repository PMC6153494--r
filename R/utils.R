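# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phenotype codes recognised by the package
#'
#' `CD`, `UC` and `IBDU` all count as IBD-affected; `unaffected` and
#' `unknown` do not.
#'
#' @keywords internal
PHENOTYPE_LEVELS <- c("CD", "UC", "IBDU", "unaffected", "unknown")

#' Does a subtype phenotype match an analysis phenotype?
#'
#' @param pheno character vector of individual phenotypes
#'   (one of `CD`, `UC`, `IBDU`, `unaffected`, `unknown`).
#' @param phenotype analysis phenotype: `"IBD"` (CD + UC + IBD-U), `"CD"`
#'   or `"UC"`.
#' @param include_ibdu_in_cd count IBD-U individuals as CD-affected in
#'   CD-specific analyses? Default `FALSE` (IBD-U contributes to the
#'   composite IBD phenotype only).
#' @return logical vector.
#' @export
pheno_matches <- function(pheno, phenotype = c("IBD", "CD", "UC"),
                          include_ibdu_in_cd = FALSE) {
  phenotype <- match.arg(phenotype)
  switch(phenotype,
    IBD = pheno %in% c("CD", "UC", "IBDU"),
    CD  = pheno == "CD" | (include_ibdu_in_cd & pheno == "IBDU"),
    UC  = pheno == "UC"
  )
}

# stop() with a classed condition so tests can assert on error type
stop_famrvar <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "famrvar_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# deterministic child seed < 2^31 derived from a parent seed and a tag
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  tagval <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + tagval) %% 2147483647)
}
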