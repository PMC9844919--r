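## ---------------------------------------------------------------------------
## End-to-end runs: balanced ensemble -> penalized fits -> rank scores ->
## changepoint selection; plus the simulation-grid driver, permutation
## false-discovery checks and cost accounting.
## ---------------------------------------------------------------------------

#' Run the full stable ranking and selection pipeline
#'
#' Executes the three algorithm stages on an imbalanced dataset:
#' (1) draw `M` balanced case-control samples, (2) fit the chosen penalized
#' logistic model to each and aggregate standardized-coefficient ranks into
#' per-covariate rank scores, (3) threshold the sorted scores by a single
#' mean-changepoint. Covariates never supported (rank score 0) are excluded
#' from the changepoint sequence and classified as noise. Deterministic given
#' `seed`.
#'
#' @param dataset a [labeled_design()].
#' @param method `"lasso"`, `"adalasso"` or `"ridge"`.
#' @param M ensemble size (default 100).
#' @param K CV folds (default 10).
#' @param lambda_rule `"min"` or `"1se"`.
#' @param seed integer master seed.
#' @param workers parallel workers (default 1; results are worker-invariant).
#' @param out_dir optional directory; when given, rank table CSV, ensemble
#'   matrix CSV, selection JSON and a reproducibility manifest are written.
#' @return an object of class `svrs_result`: `ranks` (a `rank_result`),
#'   `selection` (list: `tau`, `selected` covariate indices,
#'   `threshold_score`, `degenerate`), `ensemble` (a `coef_ensemble`),
#'   `config`.
#' @export
run_svrs <- function(dataset, method = c("lasso", "adalasso", "ridge"),
                     M = 100, K = 10, lambda_rule = c("min", "1se"),
                     seed, workers = 1L, out_dir = NULL) {
  method <- match.arg(method)
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(inherits(dataset, "labeled_design"))
  samples <- make_balanced_ensemble(dataset, M, derive_seed(seed, 1000L))
  ens <- build_ensemble(samples, method = method, K = K,
                        lambda_rule = lambda_rule,
                        base_seed = derive_seed(seed, 2000L),
                        workers = workers)
  rr <- rank_scores(ens)
  scored <- which(rr$rank_scores > 0)
  if (length(scored) < 2L)
    stop_invalid("fewer than 2 supported covariates; nothing to threshold")
  ord <- scored[order(-rr$rank_scores[scored], scored)]
  cp <- changepoint_threshold(rr$rank_scores[ord])
  selected <- sort(ord[seq_len(cp$tau)])
  result <- structure(list(
    ranks = rr,
    selection = list(tau = cp$tau, selected = selected,
                     threshold_score = cp$threshold_score,
                     degenerate = cp$degenerate),
    ensemble = ens,
    config = list(method = method, M = M, K = K, lambda_rule = lambda_rule,
                  seed = as.integer(seed), workers = workers)),
    class = "svrs_result")
  if (!is.null(out_dir)) .persist_svrs(result, out_dir)
  result
}

#' @export
print.svrs_result <- function(x, ...) {
  cat(sprintf("svrs_result (%s, M = %d, lambda_%s): %d covariates selected of %d\n",
              x$config$method, x$ranks$M_used, x$config$lambda_rule,
              length(x$selection$selected), length(x$ranks$rank_scores)))
  cat("selected:", paste(names(x$ranks$rank_scores)[x$selection$selected],
                         collapse = ", "), "\n")
  invisible(x)
}

.persist_svrs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(rank_table(result$ranks), file.path(out_dir, "rank_scores.csv"))
  data.table::fwrite(as.data.frame(result$ensemble$B), file.path(out_dir, "ensemble.csv"))
  jsonlite::write_json(
    list(tau = result$selection$tau,
         selected = result$selection$selected,
         selected_names = names(result$ranks$rank_scores)[result$selection$selected],
         threshold_score = result$selection$threshold_score,
         degenerate = result$selection$degenerate),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    c(result$config,
      list(package_version = as.character(utils::packageVersion("svrs")),
           r_version = R.version.string, timestamp_utc = format(Sys.time(), tz = "UTC"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Permute dataset columns
#'
#' Independently row-permutes each listed covariate column (distinct derived
#' seeds per column), destroying its relationship with the response while
#' preserving its marginal distribution exactly. Untouched columns and the
#' response are preserved bit-exactly.
#'
#' @param dataset a [labeled_design()].
#' @param indices integer column indices to permute.
#' @param seed integer master seed.
#' @return a new [labeled_design()].
#' @export
permute_columns <- function(dataset, indices, seed) {
  stopifnot(inherits(dataset, "labeled_design"))
  indices <- as.integer(indices)
  p <- ncol(dataset$X)
  if (any(indices < 1L | indices > p)) stop_invalid("column index out of range")
  X <- dataset$X
  n <- nrow(X)
  for (k in seq_along(indices)) {
    j <- indices[k]
    perm <- with_seed(derive_seed(seed, j), sample.int(n))
    X[, j] <- X[perm, j]
  }
  labeled_design(X, dataset$y)
}

#' Computational cost ratios of full-data fitting vs subsampled fitting
#'
#' Using the dominant `O(n p^2 (K - 1))` term of the cross-validated Lasso
#' cost (the shared `p^3` term cancels), fitting the full dataset of size `n`
#' costs `n / (2 n1)` times one balanced fit, and `n / (2 n1 M)` times the
#' whole `M`-fit ensemble.
#'
#' @param n full dataset size (`> 2 n1`).
#' @param n1 case count.
#' @param M ensemble size.
#' @return list with `full_vs_single` and `full_vs_svrs`.
#' @export
cost_ratio <- function(n, n1, M) {
  if (!(n > 2 * n1) || n1 < 1) stop_invalid("need n > 2 * n1 >= 2")
  if (M < 1) stop_invalid("M must be >= 1")
  list(full_vs_single = n / (2 * n1), full_vs_svrs = n / (2 * n1 * M))
}

#' Run a simulation grid
#'
#' For every cell of `models x I_values x nb_values x methods`: simulate a
#' full imbalanced dataset, run the stable selection pipeline, and score the
#' selection against the generating truth; for hard-shrinkage methods, also
#' record the mean per-fit metrics. Per-cell failures are recorded as rows
#' with a failure code, never aborting the grid.
#'
#' @param models character vector of model ids.
#' @param I_values integer imbalance ratios.
#' @param nb_values even integer balanced sizes.
#' @param methods character vector of fitting methods.
#' @param M ensemble size (default 100; the full-scale experiment uses 500).
#' @param K CV folds.
#' @param lambda_rule `"min"` or `"1se"`.
#' @param base_seed integer master seed; each cell derives its own.
#' @param workers parallel workers per pipeline run.
#' @param out_csv optional path for the long-format results CSV.
#' @return data.frame with one row per cell: model, I, nb, method, status,
#'   tau, TP, FP, TPR, FPR, FDR, AUC, and `ind_*` mean per-fit metrics.
#' @export
run_simulation_grid <- function(models, I_values, nb_values,
                                methods = "lasso", M = 100, K = 10,
                                lambda_rule = "min", base_seed,
                                workers = 1L, out_csv = NULL) {
  grid <- expand.grid(model = models, I = I_values, nb = nb_values,
                      method = methods, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cell <- grid[g, ]
    base <- data.frame(model = cell$model, I = cell$I, nb = cell$nb,
                       method = cell$method, status = "ok",
                       tau = NA_integer_, TP = NA_real_, FP = NA_real_,
                       TPR = NA_real_, FPR = NA_real_, FDR = NA_real_,
                       AUC = NA_real_, ind_TPR = NA_real_, ind_FPR = NA_real_,
                       ind_FDR = NA_real_, ind_AUC = NA_real_)
    tryCatch({
      cseed <- derive_seed(base_seed, g)
      des <- sim_design(cell$model, cell$I, cell$nb, seed = cseed)
      sim <- simulate_dataset(des)
      res <- run_svrs(sim$data, method = cell$method, M = M, K = K,
                      lambda_rule = lambda_rule,
                      seed = derive_seed(cseed, 1L), workers = workers)
      met <- selection_metrics(res$selection$selected, sim$truth)
      base[c("tau", "TP", "FP", "TPR", "FPR", "FDR", "AUC")] <-
        c(res$selection$tau, met$TP, met$FP, met$TPR, met$FPR, met$FDR, met$AUC)
      if (cell$method %in% c("lasso", "adalasso")) {
        ind <- evaluate_individual_fits(res$ensemble, sim$truth)$means
        base[c("ind_TPR", "ind_FPR", "ind_FDR", "ind_AUC")] <-
          ind[c("TPR", "FPR", "FDR", "AUC")]
      }
      base
    }, error = function(e) {
      base$status <- paste0("failed: ", conditionMessage(e))
      base
    })
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) data.table::fwrite(out, out_csv)
  out
}
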