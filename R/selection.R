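## ---------------------------------------------------------------------------
## Threshold sorted rank scores by a single mean-changepoint (AMOC) and score
## the resulting selection against a known signal/noise truth partition.
## ---------------------------------------------------------------------------

#' Single mean-changepoint threshold on sorted rank scores
#'
#' Given scores sorted in decreasing order, finds the split
#' `tau in 1..(v-1)` minimizing the pooled within-segment sum of squared
#' errors `SSE(r_1..r_tau) + SSE(r_{tau+1}..r_v)` (the normal-likelihood
#' single mean-change statistic, no penalty). Positions `1..tau` form the
#' selected (high-score) segment. SSE ties are broken toward the smaller
#' `tau`. Constant score vectors are degenerate: `tau = v - 1` is returned
#' with `degenerate = TRUE` and a warning.
#'
#' @param scores numeric vector sorted in decreasing order, length >= 2.
#' @return an object of class `selection_outcome`: `tau`, `selected`
#'   (positions `1..tau`), `threshold_score` (smallest selected score),
#'   `degenerate` flag, `sse` (the minimized pooled SSE).
#' @export
changepoint_threshold <- function(scores) {
  v <- length(scores)
  scores <- unname(as.numeric(scores))
  if (v < 2L) stop_invalid("need at least 2 scores to place a changepoint")
  if (is.unsorted(rev(scores))) stop_invalid("scores must be sorted in decreasing order")
  if (max(scores) - min(scores) <= 0) {
    warning(warningCondition("constant scores: no mean change detectable",
                             class = "svrs_degenerate_scores"))
    return(structure(list(tau = v - 1L, selected = seq_len(v - 1L),
                          threshold_score = scores[v - 1L],
                          degenerate = TRUE, sse = 0),
                     class = "selection_outcome"))
  }
  ## pooled SSE via prefix sums: SSE(a..b) = S2 - S^2 / m
  cs <- cumsum(scores)
  cs2 <- cumsum(scores^2)
  t <- seq_len(v - 1L)
  sse_left <- cs2[t] - cs[t]^2 / t
  sse_right <- (cs2[v] - cs2[t]) - (cs[v] - cs[t])^2 / (v - t)
  total <- sse_left + sse_right
  tau <- which.min(total)   # first minimum = smallest tau on ties
  structure(list(tau = tau, selected = seq_len(tau),
                 threshold_score = scores[tau],
                 degenerate = FALSE, sse = total[tau]),
            class = "selection_outcome")
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat(sprintf("selection_outcome: tau = %d selected (threshold score %.3f)%s\n",
              x$tau, x$threshold_score,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Selection performance against a truth partition
#'
#' `TPR = TP / s`, `FPR = FP / m`, `FDR = FP / (TP + FP)` (0/0 counted as 0),
#' and `AUC = (1 + TPR - FPR) / 2`, the ROC area of a binary selection rule.
#'
#' @param selected integer index set of selected covariates.
#' @param truth a [truth_manifest()].
#' @return list with `TP`, `FP`, `TPR`, `FPR`, `FDR`, `AUC`.
#' @export
selection_metrics <- function(selected, truth) {
  stopifnot(inherits(truth, "truth_manifest"))
  s <- length(truth$signal_indices); m <- length(truth$noise_indices)
  if (s == 0L || m == 0L) stop_invalid("truth must partition covariates into nonempty signal and noise sets")
  selected <- unique(as.integer(selected))
  TP <- sum(selected %in% truth$signal_indices)
  FP <- sum(selected %in% truth$noise_indices)
  TPR <- TP / s
  FPR <- FP / m
  FDR <- if (TP + FP == 0L) 0 else FP / (TP + FP)
  list(TP = TP, FP = FP, TPR = TPR, FPR = FPR, FDR = FDR,
       AUC = (1 + TPR - FPR) / 2)
}

#' Per-fit selection metrics across an ensemble
#'
#' For hard-shrinkage methods, each individual fit performs its own variable
#' selection: fit `j` selects the covariates with nonzero coefficients.
#' Returns the per-fit metric distribution together with its means (the
#' quantities reported in parentheses alongside ensemble results). Ridge
#' performs no automatic selection and is rejected.
#'
#' @param ensemble a `coef_ensemble` from [build_ensemble()].
#' @param truth a [truth_manifest()].
#' @param tol numerical-zero tolerance.
#' @return list with `per_fit` (data.frame of M rows: TP, FP, TPR, FPR, FDR,
#'   AUC) and `means` (named vector of column means).
#' @export
evaluate_individual_fits <- function(ensemble, truth, tol = .svrs_zero_tol) {
  stopifnot(inherits(ensemble, "coef_ensemble"))
  if (ensemble$method == "ridge")
    stop(errorCondition("ridge performs no automatic selection; individual-fit metrics are not applicable",
                        class = c("svrs_unsupported_method", "error")))
  rows <- lapply(seq_len(nrow(ensemble$B)), function(j) {
    sel <- which(abs(ensemble$B[j, ]) > tol)
    as.data.frame(selection_metrics(sel, truth))
  })
  per_fit <- do.call(rbind, rows)
  list(per_fit = per_fit, means = colMeans(per_fit))
}
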