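## ---------------------------------------------------------------------------
## Cross-validated penalized logistic regression on balanced samples.
## Backed by glmnet; the tuning parameter is chosen on a log-spaced path by
## K-fold cross-validated AUC with stratified folds.
## ---------------------------------------------------------------------------

## stratified fold assignment: both classes represented in every fold
.stratified_folds <- function(y, K, seed) {
  with_seed(seed, {
    foldid <- integer(length(y))
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep_len(seq_len(K), length(idx)))
    }
    foldid
  })
}

.extract_fit <- function(cv, lambda_rule) {
  lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  i <- which(cv$lambda == lam)[1]
  co <- as.numeric(stats::coef(cv$glmnet.fit, s = lam))
  list(lambda = lam, intercept = co[1], beta = co[-1], cvm = cv$cvm[i])
}

#' Adaptive-Lasso penalty weights
#'
#' `w_j = 1 / |beta_j|^gamma` for nonzero initial estimates; covariates with a
#' zero initial estimate receive infinite weight, which excludes them from the
#' second-stage fit (their coefficient is forced to zero).
#'
#' @param beta_init initial coefficient vector (a converged Lasso solution on
#'   the same sample).
#' @param gamma positive exponent (default 1).
#' @return weight vector; all-`Inf` (with a warning of class
#'   `svrs_empty_model`) when every initial estimate is zero.
#' @export
adalasso_weights <- function(beta_init, gamma = 1) {
  if (gamma <= 0) stop_invalid("gamma must be positive")
  a <- abs(beta_init)
  w <- ifelse(a > .svrs_zero_tol, 1 / a^gamma, Inf)
  if (all(is.infinite(w)))
    warning(warningCondition("initial Lasso solution is empty; second stage skipped",
                             class = "svrs_empty_model"))
  w
}

#' Fit a cross-validated penalized logistic regression
#'
#' Fits Lasso (`l1`), adaptive Lasso (two-stage weighted `l1` with Lasso
#' initial estimates, `gamma = 1`) or ridge (`l2`) logistic regression on a
#' balanced sample. `lambda` is selected on a 100-value log-spaced path by
#' K-fold cross-validated AUC with stratified folds: `lambda_rule = "min"`
#' maximizes mean CV AUC; `"1se"` takes the largest `lambda` within one
#' standard error of the maximum. Constant covariates are dropped with a
#' warning and receive coefficient 0.
#'
#' @param sample a `balanced_sample` (or any [labeled_design()]).
#' @param method `"lasso"`, `"adalasso"` or `"ridge"`.
#' @param K number of CV folds (default 10).
#' @param lambda_rule `"min"` or `"1se"`.
#' @param seed integer seed (governs fold assignment; the fit is deterministic
#'   given the seed).
#' @param gamma adaptive-Lasso weight exponent (default 1).
#' @param nlambda path length (default 100).
#' @return an object of class `fit_result`: `method`, `coefficients` (named,
#'   original covariate scale), `intercept`, `lambda_chosen`, `lambda_rule`,
#'   `cv_criterion` (mean CV AUC at the chosen lambda), `sds` (covariate
#'   standard deviations in the fitted sample), `seed`, `empty` flag.
#' @export
fit_penalized_logistic <- function(sample,
                                   method = c("lasso", "adalasso", "ridge"),
                                   K = 10, lambda_rule = c("min", "1se"),
                                   seed, gamma = 1, nlambda = 100) {
  method <- match.arg(method)
  lambda_rule <- match.arg(lambda_rule)
  data <- if (inherits(sample, "balanced_sample")) sample$data else sample
  stopifnot(inherits(data, "labeled_design"))
  X <- data$X; y <- data$y
  if (length(unique(y)) < 2L) stop_invalid("sample contains a single response class")
  p <- ncol(X)
  sds <- apply(X, 2, sd)
  keep <- sds > 0
  if (!all(keep))
    warning(sprintf("dropping %d constant covariate(s); coefficients set to 0",
                    sum(!keep)))
  Xk <- X[, keep, drop = FALSE]
  foldid <- .stratified_folds(y, K, derive_seed(seed, 101L))
  alpha_gl <- if (method == "ridge") 0 else 1

  pf <- rep(1, ncol(Xk))
  empty <- FALSE
  if (method == "adalasso") {
    cv0 <- glmnet::cv.glmnet(Xk, y, family = "binomial", alpha = 1,
                             type.measure = "auc", foldid = foldid,
                             nlambda = nlambda, standardize = TRUE)
    b0 <- .extract_fit(cv0, "min")$beta
    pf <- withCallingHandlers(
      adalasso_weights(b0, gamma),
      svrs_empty_model = function(w) { empty <<- TRUE; invokeRestart("muffleWarning") })
    if (empty) {
      beta_full <- numeric(p); names(beta_full) <- colnames(X)
      fr <- .extract_fit(cv0, lambda_rule)
      return(structure(list(method = method, coefficients = beta_full,
                            intercept = fr$intercept, lambda_chosen = fr$lambda,
                            lambda_rule = lambda_rule, cv_criterion = fr$cvm,
                            sds = sds, seed = as.integer(seed), empty = TRUE),
                       class = "fit_result"))
    }
  }

  cv <- tryCatch(
    glmnet::cv.glmnet(Xk, y, family = "binomial", alpha = alpha_gl,
                      type.measure = "auc", foldid = foldid,
                      nlambda = nlambda, penalty.factor = pf,
                      standardize = TRUE),
    error = function(e) stop_convergence(paste0("glmnet failed: ", conditionMessage(e))))
  fr <- .extract_fit(cv, lambda_rule)
  beta_full <- numeric(p); names(beta_full) <- colnames(X)
  beta_full[keep] <- fr$beta
  structure(list(method = method, coefficients = beta_full,
                 intercept = fr$intercept, lambda_chosen = fr$lambda,
                 lambda_rule = lambda_rule, cv_criterion = fr$cvm,
                 sds = sds, seed = as.integer(seed), empty = empty),
            class = "fit_result")
}

#' Standardized coefficients
#'
#' `beta^Delta_i = sd(x_i) * beta_i`: the coefficient each covariate would
#' carry if fitted on its standardized scale, used as the scale-free effect
#' size for ranking.
#'
#' @param fit a `fit_result`.
#' @return named length-p numeric vector.
#' @export
standardize_coefficients <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  if (is.null(fit$sds)) stop_invalid("fit carries no covariate standard deviations")
  fit$sds * fit$coefficients
}

#' Build a coefficient ensemble from balanced samples
#'
#' Fits the chosen penalized model to each balanced sample and assembles the
#' `M x p` matrix of standardized coefficients. Per-fit seeds are derived from
#' `base_seed` and the sample index, so results are identical for any worker
#' count. Individual fit failures are tolerated up to `max_fail_frac`; failed
#' rows are dropped (with `M` reduced) and recorded.
#'
#' @param samples list of `balanced_sample` objects sharing one covariate
#'   schema.
#' @param method,K,lambda_rule,gamma,nlambda passed to
#'   [fit_penalized_logistic()].
#' @param base_seed integer master seed.
#' @param workers parallel workers via `parallel::mclapply` (default 1).
#' @param max_fail_frac maximum tolerated fraction of failed fits (default 0.1).
#' @return an object of class `coef_ensemble`: `B` (`M x p` standardized
#'   coefficient matrix), `fits` (per-fit metadata), `method`,
#'   `covariate_names`, `failed` (indices of dropped fits).
#' @export
build_ensemble <- function(samples, method = c("lasso", "adalasso", "ridge"),
                           K = 10, lambda_rule = c("min", "1se"), base_seed,
                           workers = 1L, gamma = 1, nlambda = 100,
                           max_fail_frac = 0.1) {
  method <- match.arg(method)
  lambda_rule <- match.arg(lambda_rule)
  M <- length(samples)
  if (M < 1) stop_invalid("need at least one balanced sample")
  one <- function(j) {
    tryCatch(
      fit_penalized_logistic(samples[[j]], method = method, K = K,
                             lambda_rule = lambda_rule,
                             seed = derive_seed(base_seed, j),
                             gamma = gamma, nlambda = nlambda),
      error = function(e) e)
  }
  fits <- if (workers > 1L)
    parallel::mclapply(seq_len(M), one, mc.cores = workers) else
    lapply(seq_len(M), one)
  failed <- which(vapply(fits, inherits, logical(1), "error"))
  if (length(failed) > max_fail_frac * M)
    stop_convergence(sprintf("%d of %d fits failed (> %.0f%% tolerated)",
                             length(failed), M, 100 * max_fail_frac))
  ok <- setdiff(seq_len(M), failed)
  B <- t(vapply(fits[ok], standardize_coefficients,
                numeric(ncol(samples[[1]]$data$X))))
  colnames(B) <- colnames(samples[[1]]$data$X)
  structure(list(B = B, fits = fits[ok], method = method,
                 covariate_names = colnames(B), failed = failed),
            class = "coef_ensemble")
}

#' @export
print.coef_ensemble <- function(x, ...) {
  cat(sprintf("coef_ensemble: %s, M = %d fits x p = %d covariates (%d failed)\n",
              x$method, nrow(x$B), ncol(x$B), length(x$failed)))
  invisible(x)
}
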