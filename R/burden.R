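# Firth-penalized logistic regression (Jeffreys prior), used as the
# fallback when the ML fit separates. Returns penalized log-likelihood.
.firth_logistic <- function(X, y, max_iter = 50L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * w
    info <- crossprod(X, XW)
    info_inv <- solve(info)
    h <- rowSums((X %*% info_inv) * XW)
    score <- crossprod(X, (y - mu) + h * (0.5 - mu))
    step <- info_inv %*% score
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  mu <- stats::plogis(eta)
  ll <- sum(y * log(mu) + (1 - y) * log1p(-mu)) +
    0.5 * determinant(crossprod(X, X * mu * (1 - mu)))$modulus
  list(beta = beta, loglik = as.numeric(ll))
}

#' Combined multivariate and collapsing (CMC) gene-burden test
#'
#' Damaging variants in a gene are collapsed into two per-sample binary
#' carrier indicators by population AF bin (AF < `af_split`, and
#' `af_split` <= AF < `af_max`; the per-variant AF follows the
#' AJ -> NFE -> proximal-AJ fallback). Case status is modeled by logistic
#' regression on the indicators plus the first `n_pcs` ancestry PCs; the
#' log-likelihood ratio against the PC-only null is referred to a
#' chi-squared distribution with one degree of freedom per non-empty
#' bin.
#'
#' @param geno samples x variants dosage matrix for one gene (damaging
#'   variants only).
#' @param case_status logical (or 0/1) vector per sample.
#' @param pcs samples x >=`n_pcs` matrix of ancestry PCs.
#' @param af per-variant population AF, AJ-first fallback already
#'   applied (see [control_af()] sources).
#' @param af_split,af_max bin edges (defaults 0.01 and 0.05).
#' @param n_pcs covariate PCs (default 5).
#' @return list: `llr`, `df`, `p`, `n_carriers_rare`,
#'   `n_carriers_low_freq`, `separated` (Firth fallback used?).
#' @export
cmc_burden_test <- function(geno, case_status, pcs, af,
                            af_split = 0.01, af_max = 0.05, n_pcs = 5L) {
  geno <- as.matrix(geno)
  y <- as.numeric(case_status)
  stopifnot(length(y) == nrow(geno), length(af) == ncol(geno),
            all(y %in% c(0, 1)))
  pcs <- as.matrix(pcs)[, seq_len(min(n_pcs, ncol(as.matrix(pcs)))),
                        drop = FALSE]
  in_rare <- af < af_split
  in_low <- af >= af_split & af < af_max
  carrier <- function(sel) {
    if (!any(sel)) return(rep(0, nrow(geno)))
    as.numeric(rowSums(geno[, sel, drop = FALSE] >= 1, na.rm = TRUE) > 0)
  }
  b1 <- carrier(in_rare)
  b2 <- carrier(in_low)
  bins <- list()
  if (stats::var(b1) > 0) bins$rare <- b1
  if (stats::var(b2) > 0) bins$low_freq <- b2
  if (length(bins) == 0)
    return(list(llr = 0, df = 0L, p = 1,
                n_carriers_rare = sum(b1), n_carriers_low_freq = sum(b2),
                separated = FALSE))
  X0 <- cbind(1, pcs)
  X1 <- cbind(X0, do.call(cbind, bins))
  separated <- FALSE
  fit_ll <- function(X) {
    w <- NULL
    fit <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial()),
      warning = function(cnd) {
        w <<- conditionMessage(cnd)
        invokeRestart("muffleWarning")
      })
    mu <- fit$fitted.values
    if (!is.null(w) && grepl("fitted probabilities", w)) {
      separated <<- TRUE
      return(NA_real_)
    }
    sum(y * log(mu) + (1 - y) * log1p(-mu))
  }
  ll0 <- fit_ll(X0)
  ll1 <- fit_ll(X1)
  if (separated || is.na(ll0) || is.na(ll1)) {
    separated <- TRUE
    ll0 <- .firth_logistic(X0, y)$loglik
    ll1 <- .firth_logistic(X1, y)$loglik
  }
  llr <- max(0, 2 * (ll1 - ll0))
  df <- length(bins)
  list(llr = llr, df = df,
       p = stats::pchisq(llr, df = df, lower.tail = FALSE),
       n_carriers_rare = sum(b1), n_carriers_low_freq = sum(b2),
       separated = separated)
}
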