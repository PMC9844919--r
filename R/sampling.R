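## ---------------------------------------------------------------------------
## Response-based (case-control) downsampling: keep every case, draw an equal
## number of controls without replacement. The induced intercept bias equals
## log(p1/p0) with p1 = 1 and p0 = n1/n0 (the control sampling fraction).
## ---------------------------------------------------------------------------

#' Intercept offset induced by balanced case-control sampling
#'
#' Under balanced downsampling all cases are retained (`p1 = 1`) and controls
#' are sampled with fraction `p0 = n1 / n0`, inflating the intercept of the
#' sampled-data logistic model by `log(p1 / p0) = log(n0 / n1)`. A full-data
#' intercept is recovered as `alpha = alpha_balanced - log(n0 / n1)`.
#'
#' @param n0 control count in the source data.
#' @param n1 case count in the source data.
#' @return the offset `log(n0 / n1)`.
#' @export
sampling_offset <- function(n0, n1) {
  if (n0 < 1 || n1 < 1) stop_invalid("n0 and n1 must be >= 1")
  log(n0 / n1)
}

#' Downsample controls to a balanced dataset
#'
#' Retains all `n1` cases and draws a simple random sample of `n1` controls
#' without replacement, giving a balanced dataset of size `n_b = 2 n1`. Rows
#' are shuffled deterministically by `seed` so downstream CV folds are not
#' accidentally stratified by row order. The offset is carried as metadata
#' only; models are fitted on the balanced data without it (slope coefficients
#' are unaffected by the intercept shift).
#'
#' @param dataset a [labeled_design()] with at least as many controls as cases.
#' @param seed integer seed.
#' @return an object of class `balanced_sample`: list with `data`
#'   (a [labeled_design()] of size `2 n1`), `n0`, `n1`, `p1`, `p0`, `offset`,
#'   `source_seed` and `control_rows` (source row indices of sampled controls).
#' @export
downsample_balanced <- function(dataset, seed) {
  stopifnot(inherits(dataset, "labeled_design"))
  case_rows <- which(dataset$y == 1L)
  ctrl_rows <- which(dataset$y == 0L)
  n1 <- length(case_rows); n0 <- length(ctrl_rows)
  if (n1 < 1) stop_invalid("dataset has no cases")
  if (n0 < n1) stop_invalid("majority class smaller than minority")
  with_seed(seed, {
    picked <- if (n0 == n1) ctrl_rows else ctrl_rows[sample.int(n0, n1)]
    rows <- c(case_rows, picked)
    shuffle <- sample.int(2L * n1)
    rows <- rows[shuffle]
    structure(list(
      data = labeled_design(dataset$X[rows, , drop = FALSE], dataset$y[rows]),
      n0 = n0, n1 = n1, p1 = 1, p0 = n1 / n0,
      offset = sampling_offset(n0, n1),
      source_seed = as.integer(seed),
      control_rows = sort(picked)), class = "balanced_sample")
  })
}

#' @export
print.balanced_sample <- function(x, ...) {
  cat(sprintf("balanced_sample: n_b = %d (n1 = %d of %d cases kept, %d of %d controls), offset = %.4f\n",
              2L * x$n1, x$n1, x$n1, x$n1, x$n0, x$offset))
  invisible(x)
}

#' Draw an ensemble of balanced samples
#'
#' Produces `M` balanced samples from one imbalanced dataset. The case block
#' is identical across samples; control draws are independent across samples,
#' with each sample's seed derived from `base_seed` and its index so results
#' do not depend on evaluation order.
#'
#' @param dataset a [labeled_design()].
#' @param M number of balanced samples (>= 1).
#' @param base_seed integer master seed.
#' @return list of `M` `balanced_sample` objects.
#' @export
make_balanced_ensemble <- function(dataset, M, base_seed) {
  if (M < 1) stop_invalid("M must be >= 1")
  lapply(seq_len(M), function(j) downsample_balanced(dataset, derive_seed(base_seed, j)))
}
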