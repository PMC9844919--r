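## ---------------------------------------------------------------------------
## Aggregate rank scores from an M x p standardized-coefficient ensemble.
## Within each fit, covariates are ranked 1..p by increasing |beta^Delta|
## (rank p = largest); a covariate zeroed out in a fit contributes 0 to its
## score for that fit, so Rank(X_i) = M^-1 sum_j R_ij 1[|beta^Delta_ij| > 0].
## ---------------------------------------------------------------------------

#' Within-fit ranks of absolute standardized coefficients
#'
#' Returns a permutation of `1..p`: the largest `|beta^Delta|` receives rank
#' `p`, the smallest rank 1. Entries below the numerical-zero tolerance are
#' treated as exactly zero and occupy the lowest positions. All ties
#' (including among zeros) are broken by ascending covariate index, making
#' the ranking deterministic.
#'
#' @param betaD_row length-p numeric vector of standardized coefficients.
#' @param tol numerical-zero tolerance (default `1e-10`).
#' @return integer vector of ranks.
#' @export
assign_ranks <- function(betaD_row, tol = .svrs_zero_tol) {
  if (!is.numeric(betaD_row) || anyNA(betaD_row) || any(!is.finite(betaD_row)))
    stop_invalid("betaD_row must be finite numeric")
  a <- abs(betaD_row)
  a[a < tol] <- 0
  p <- length(a)
  r <- integer(p)
  r[order(a, seq_len(p))] <- seq_len(p)
  r
}

#' Aggregate rank scores from a coefficient ensemble
#'
#' Computes, for each covariate, the mean across fits of its within-fit rank
#' with zeroed-out coefficients contributing nothing:
#' `Rank(X_i) = M^-1 sum_j R_ij 1[|beta^Delta_ij| > 0]`.
#' Also returns the support set (covariates nonzero in at least one fit), the
#' per-covariate drop fraction `p_drop_i = M^-1 sum_j 1[beta_ij = 0]`, and the
#' effective maximum rank `p_EF` (the number of rank positions carrying
#' nonzero coefficient mass across the ensemble). When no coefficient is zero
#' anywhere, the scores sum exactly to `p (p + 1) / 2`.
#'
#' @param B `M x p` matrix of standardized coefficients (or a
#'   `coef_ensemble`).
#' @param tol numerical-zero tolerance.
#' @return an object of class `rank_result`: `rank_scores` (named length-p),
#'   `support` (integer index set), `p_EF`, `p_drop`, `M_used`.
#' @export
rank_scores <- function(B, tol = .svrs_zero_tol) {
  if (inherits(B, "coef_ensemble")) B <- B$B
  B <- as.matrix(B)
  if (nrow(B) < 1L || ncol(B) < 1L) stop_invalid("B must be a nonempty M x p matrix")
  M <- nrow(B); p <- ncol(B)
  A <- abs(B)
  A[A < tol] <- 0
  nz <- A > 0
  R <- t(apply(A, 1L, function(row) {
    r <- integer(p); r[order(row, seq_len(p))] <- seq_len(p); r
  }))
  if (p == 1L) R <- matrix(R, M, 1L)   # apply() drops to a vector
  scores <- colSums(R * nz) / M
  names(scores) <- colnames(B)
  ## mass carried at each rank position h across fits
  pos_mass <- numeric(p)
  for (j in seq_len(M)) {
    ord <- order(R[j, ])
    pos_mass <- pos_mass + A[j, ord]
  }
  structure(list(rank_scores = scores,
                 support = which(colSums(nz) > 0L),
                 p_EF = sum(pos_mass > 0),
                 p_drop = colMeans(!nz),
                 M_used = M),
            class = "rank_result")
}

#' @export
print.rank_result <- function(x, ...) {
  cat(sprintf("rank_result: p = %d covariates, M = %d fits, |support| = %d, p_EF = %d\n",
              length(x$rank_scores), x$M_used, length(x$support), x$p_EF))
  invisible(x)
}

#' Sorted rank-score listing
#'
#' Covariates sorted by decreasing rank score, ties broken by ascending
#' covariate index (stable and deterministic).
#'
#' @param result a `rank_result`.
#' @param names optional covariate names (defaults to names stored in the
#'   result, else `X1..Xp`).
#' @return data.frame with columns `covariate`, `index`, `rank_score`,
#'   `p_drop`, `in_support`.
#' @export
rank_table <- function(result, names = NULL) {
  stopifnot(inherits(result, "rank_result"))
  p <- length(result$rank_scores)
  if (is.null(names)) names <- names(result$rank_scores)
  if (is.null(names)) names <- paste0("X", seq_len(p))
  ord <- order(-result$rank_scores, seq_len(p))
  data.frame(covariate = names[ord], index = ord,
             rank_score = unname(result$rank_scores[ord]),
             p_drop = unname(result$p_drop[ord]),
             in_support = ord %in% result$support,
             row.names = NULL)
}
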