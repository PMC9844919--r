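## ---------------------------------------------------------------------------
## Synthetic imbalanced binary data: four logistic simulation designs with
## independent (UNCOR) or correlated (COR) signal and noise covariates.
## Correlated discrete covariates use the NORTA construction: equicorrelated
## standard normals thresholded at the marginal quantiles.
## ---------------------------------------------------------------------------

.sim_coefs <- list(
  s12 = c(-0.9, -0.8, -0.7, -0.6, -0.5, -0.4, 1.0, 1.1, 1.2, 1.3, 1.4, 1.5),
  s24 = c(-1.20, -1.10, -1.00, -0.90, -0.80, -0.70, -0.60, -0.50, -0.40, -0.30,
          -0.20, -0.10, 0.05, 0.15, 0.25, 0.35, 0.45, 0.55, 0.65, 0.75, 0.85,
          0.95, 1.05, 1.15))

#' Simulation design specification
#'
#' Defines one of the four built-in simulation models. The 12-signal models
#' have p = 100 covariates (12 signal : 88 noise); the 24-signal models have
#' p = 200 (24 : 176). `COR` variants add correlated nominal clusters,
#' a correlated binary block, and an equicorrelated Gaussian block spanning
#' signal and noise covariates.
#'
#' @param model_id one of `"UNCOR-12"`, `"COR-12"`, `"UNCOR-24"`, `"COR-24"`.
#' @param imbalance_I positive integer `I` for a 1:I case:control ratio.
#' @param n_b_target even positive integer: target balanced sample size
#'   (twice the case count).
#' @param seed integer master seed for dataset generation.
#' @param latent_corr latent equicorrelation in `[0, 1)` used by the NORTA
#'   blocks and the Gaussian block of the COR models (default 0.8).
#' @param alpha optional intercept; when `NULL` it is calibrated to the target
#'   prevalence `1 / (1 + I)` by [calibrate_intercept()].
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(model_id, imbalance_I, n_b_target, seed,
                       latent_corr = 0.8, alpha = NULL) {
  model_id <- match.arg(model_id, c("UNCOR-12", "COR-12", "UNCOR-24", "COR-24"))
  if (!is.numeric(imbalance_I) || imbalance_I < 1 || imbalance_I != round(imbalance_I))
    stop_invalid("imbalance_I must be a positive integer")
  if (!is.numeric(n_b_target) || n_b_target <= 0 || n_b_target %% 2 != 0)
    stop_invalid("n_b_target must be an even positive integer")
  if (latent_corr < 0 || latent_corr >= 1)
    stop_invalid("latent_corr must lie in [0, 1)")
  s <- if (grepl("12$", model_id)) 12L else 24L
  p <- if (s == 12L) 100L else 200L
  structure(list(model_id = model_id, p = p, s = s,
                 signal_coefficients = .sim_coefs[[paste0("s", s)]],
                 alpha = alpha, latent_corr = latent_corr,
                 imbalance_I = as.integer(imbalance_I),
                 n_b_target = as.integer(n_b_target),
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("sim_design %s: p = %d (s = %d), imbalance 1:%d, n_b = %d, seed %d\n",
              x$model_id, x$p, x$s, x$imbalance_I, x$n_b_target, x$seed))
  invisible(x)
}

#' Full dataset size implied by a balanced target and an imbalance ratio
#'
#' The full dataset holds `n1 = n_b / 2` cases and `n0 = I * n1` controls,
#' so `n = (n_b / 2) * (1 + I)`.
#'
#' @param n_b even positive integer, target balanced sample size.
#' @param imbalance_I positive integer imbalance ratio 1:I.
#' @return total size `n`.
#' @export
compute_full_size <- function(n_b, imbalance_I) {
  if (!is.numeric(n_b) || n_b <= 0 || n_b %% 2 != 0)
    stop_invalid("n_b must be an even positive integer")
  if (!is.numeric(imbalance_I) || imbalance_I < 1)
    stop_invalid("imbalance_I must be >= 1")
  (n_b / 2) * (1 + imbalance_I)
}

#' Logistic transformation
#'
#' Elementwise `1 / (1 + exp(-z))`, used to map normally distributed
#' covariates onto the unit interval so coefficient magnitudes stay
#' comparable across covariates.
#'
#' @param z numeric vector.
#' @return vector in (0, 1).
#' @export
logistic_squash <- function(z) plogis(z)

## n x k equicorrelated standard normals via the one-factor construction:
## Z = sqrt(rho) W + sqrt(1 - rho) E with a shared W per row
.equicorr_normal <- function(n, k, rho) {
  if (rho < 0 || rho >= 1) stop_invalid("equicorrelation must lie in [0, 1)")
  E <- matrix(rnorm(n * k), n, k)
  if (rho == 0) return(E)
  sqrt(rho) * rnorm(n) + sqrt(1 - rho) * E
}

#' Correlated binary covariates via NORTA
#'
#' Each column is marginally Bernoulli(`marginal_p`), obtained by thresholding
#' equicorrelated standard normals at the `marginal_p` quantile; columns are
#' positively dependent for `latent_corr > 0`.
#'
#' @param n rows.
#' @param k block size (number of binary columns).
#' @param marginal_p marginal success probability in (0, 1).
#' @param latent_corr latent equicorrelation in `[0, 1)`.
#' @param seed integer seed.
#' @return `n x k` 0/1 matrix.
#' @export
norta_binary <- function(n, k, marginal_p = 0.5, latent_corr = 0.8, seed) {
  if (marginal_p <= 0 || marginal_p >= 1) stop_invalid("marginal_p must lie in (0, 1)")
  if (latent_corr < 0 || latent_corr >= 1)
    stop_invalid("latent correlation matrix must be positive definite (latent_corr in [0, 1))")
  with_seed(seed, {
    Z <- .equicorr_normal(n, k, latent_corr)
    matrix(as.double(Z < qnorm(marginal_p)), n, k)
  })
}

#' Correlated clusters of a 4-category nominal covariate via NORTA
#'
#' Each cluster is one 4-category nominal variable encoded as 4 dummy columns
#' summing to 1 per row; clusters are dependent through an equicorrelated
#' latent normal thresholded at the 0.25/0.5/0.75 normal quantiles (equal
#' marginal category probabilities). Only the first 3 dummies per cluster are
#' exported as covariates to avoid perfect multicollinearity.
#'
#' @param n rows.
#' @param n_clusters 3 or 4 clusters.
#' @param latent_corr latent equicorrelation in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `dummies` (list of `n x 4` matrices, one per cluster) and
#'   `exported` (list of `n x 3` matrices: the first 3 dummies per cluster).
#' @export
norta_nominal_clusters <- function(n, n_clusters, latent_corr = 0.8, seed) {
  if (!n_clusters %in% c(3L, 4L)) stop_invalid("n_clusters must be 3 or 4")
  if (latent_corr < 0 || latent_corr >= 1)
    stop_invalid("latent correlation matrix must be positive definite (latent_corr in [0, 1))")
  cuts <- qnorm(c(0.25, 0.5, 0.75))
  with_seed(seed, {
    Z <- .equicorr_normal(n, n_clusters, latent_corr)
    dummies <- lapply(seq_len(n_clusters), function(cl) {
      cat4 <- findInterval(Z[, cl], cuts) + 1L   # categories 1..4
      D <- matrix(0, n, 4)
      D[cbind(seq_len(n), cat4)] <- 1
      D
    })
    list(dummies = dummies,
         exported = lapply(dummies, function(D) D[, 1:3, drop = FALSE]))
  })
}

## covariate recipes -------------------------------------------------------

.simulate_covariates_impl <- function(design, n) {
  p <- design$p
  rho <- design$latent_corr
  X <- matrix(NA_real_, n, p)
  colnames(X) <- paste0("X", seq_len(p))
  switch(design$model_id,
    "UNCOR-12" = {
      X[, 1:6]    <- rbinom(n * 6, 1, 0.5)
      X[, 7:12]   <- logistic_squash(matrix(rnorm(n * 6), n, 6))
      X[, 13:18]  <- rbinom(n * 6, 1, 0.5)
      X[, 19:100] <- runif(n * 82)
    },
    "UNCOR-24" = {
      X[, 1:12]   <- rbinom(n * 12, 1, 0.5)
      X[, 13:24]  <- logistic_squash(matrix(rnorm(n * 12), n, 12))
      X[, 25:200] <- runif(n * 176)
    },
    "COR-12" = {
      s_nom <- sample.int(2^31 - 2, 1)   # block seeds drawn eagerly so the
      s_bin <- sample.int(2^31 - 2, 1)   # nominal and binary streams differ
      nom <- norta_nominal_clusters(n, 3L, rho, seed = s_nom)
      X[, 1:3]   <- nom$exported[[1]]
      X[, 4:6]   <- nom$exported[[2]]
      X[, 13:15] <- nom$exported[[3]]
      X[, 16:18] <- norta_binary(n, 3L, 0.5, rho, seed = s_bin)
      X[, 7:12]  <- logistic_squash(.equicorr_normal(n, 6, 0.8))
      X[, 19:100] <- runif(n * 82)
    },
    "COR-24" = {
      s_nom <- sample.int(2^31 - 2, 1)
      s_bin <- sample.int(2^31 - 2, 1)
      nom <- norta_nominal_clusters(n, 4L, rho, seed = s_nom)
      X[, 1:3]   <- nom$exported[[1]]
      X[, 4:6]   <- nom$exported[[2]]
      X[, 25:27] <- nom$exported[[3]]
      X[, 28:30] <- nom$exported[[4]]
      ## one 12-column latent block so the noise binaries (X31..X36) are
      ## correlated with the signal binaries (X7..X12)
      bin <- norta_binary(n, 12L, 0.5, rho, seed = s_bin)
      X[, 7:12]  <- bin[, 1:6]
      X[, 31:36] <- bin[, 7:12]
      X[, 13:24] <- logistic_squash(.equicorr_normal(n, 12, 0.8))
      X[, 37:200] <- runif(n * 164)
    },
    stop_invalid(sprintf("unknown model_id '%s'", design$model_id)))
  X
}

#' Simulate a covariate block under a simulation design
#'
#' Draws `n` covariate rows following the model-specific recipe (no
#' response). All continuous covariates lie in (0, 1); dummies in \{0, 1\}.
#'
#' @param design a [sim_design()].
#' @param n number of rows.
#' @param seed integer seed.
#' @return `n x p` matrix with columns `X1..Xp`.
#' @export
simulate_covariates <- function(design, n, seed) {
  stopifnot(inherits(design, "sim_design"))
  if (n < 1) stop_invalid("n must be >= 1")
  with_seed(seed, .simulate_covariates_impl(design, n))
}

## full-length coefficient vector of a design
.design_beta <- function(design) {
  beta <- numeric(design$p)
  beta[seq_len(design$s)] <- design$signal_coefficients
  beta
}

#' Calibrate the model intercept to a target prevalence
#'
#' Finds `alpha` such that the Monte-Carlo estimate of
#' `E[plogis(alpha + x' beta)]` over `mc_size` simulated covariate rows equals
#' `target_prevalence` within `tol`. The prevalence is strictly increasing in
#' `alpha`, so the root is found by bracketed root search starting from
#' `qlogis(target_prevalence)` with a widening margin.
#'
#' @param design a [sim_design()].
#' @param target_prevalence case probability in (0, 0.5).
#' @param mc_size Monte-Carlo sample size (default 2e5).
#' @param tol tolerance on the prevalence scale (default 1e-5).
#' @param seed integer seed (deterministic result).
#' @return the calibrated intercept `alpha`.
#' @export
calibrate_intercept <- function(design, target_prevalence, mc_size = 2e5,
                                tol = 1e-5, seed) {
  stopifnot(inherits(design, "sim_design"))
  if (target_prevalence <= 0 || target_prevalence >= 0.5)
    stop_invalid("target_prevalence must lie in (0, 0.5)")
  X <- simulate_covariates(design, mc_size, derive_seed(seed, 911L))
  eta <- drop(X %*% .design_beta(design))
  f <- function(a) mean(plogis(a + eta)) - target_prevalence
  a0 <- qlogis(target_prevalence)
  lo <- a0 - 2; hi <- a0 + 2; width <- 2
  for (i in 1:30) {
    if (f(lo) < 0 && f(hi) > 0) break
    width <- width * 2
    lo <- a0 - width; hi <- a0 + width
    if (i == 30) stop_convergence("intercept calibration: bracket expansion failed")
  }
  uniroot(f, c(lo, hi), tol = tol)$root
}

#' Simulate a full imbalanced dataset with exact class counts
#'
#' Draws covariate rows and Bernoulli responses with
#' `pi_i = plogis(alpha + x_i' beta)`, continuing until exactly
#' `n1 = n_b_target / 2` cases and `n0 = I * n1` controls are collected, so
#' the dataset size equals [compute_full_size()] deterministically. The run
#' aborts if more than 50 times the expected number of draws is needed.
#'
#' @param design a [sim_design()].
#' @param seed optional integer seed overriding `design$seed`.
#' @return list with `data` (a [labeled_design()]), `truth` (a
#'   [truth_manifest()]) and `alpha`.
#' @export
simulate_dataset <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "sim_design"))
  n1_target <- design$n_b_target %/% 2L
  n0_target <- design$imbalance_I * n1_target
  n_total <- n1_target + n0_target
  prevalence <- 1 / (1 + design$imbalance_I)
  alpha <- design$alpha
  if (is.null(alpha))
    alpha <- calibrate_intercept(design, prevalence, seed = derive_seed(seed, 7L))
  beta <- .design_beta(design)

  cases <- list(); controls <- list()
  n1 <- 0L; n0 <- 0L; drawn <- 0; batch_idx <- 0L
  while (n1 < n1_target || n0 < n0_target) {
    ## deterministic batch schedule: enough to fill the slower-filling class,
    ## with 10% headroom, capped for memory
    need_case <- (n1_target - n1) / prevalence
    need_ctrl <- (n0_target - n0) / (1 - prevalence)
    bs <- ceiling(min(max(max(need_case, need_ctrl) * 1.1, 1000), 2e5))
    batch_idx <- batch_idx + 1L
    bseed <- derive_seed(seed, batch_idx)
    X <- simulate_covariates(design, bs, bseed)
    yy <- with_seed(derive_seed(bseed, 1L),
                    rbinom(bs, 1, plogis(alpha + drop(X %*% beta))))
    drawn <- drawn + bs
    if (n1 < n1_target) {
      idx <- which(yy == 1L)
      if (length(idx)) {
        take <- head(idx, n1_target - n1)
        cases[[length(cases) + 1L]] <- X[take, , drop = FALSE]
        n1 <- n1 + length(take)
      }
    }
    if (n0 < n0_target) {
      idx <- which(yy == 0L)
      if (length(idx)) {
        take <- head(idx, n0_target - n0)
        controls[[length(controls) + 1L]] <- X[take, , drop = FALSE]
        n0 <- n0 + length(take)
      }
    }
    if (drawn > 50 * n_total)
      stop_convergence("runaway generation: cases too rare for the calibrated intercept")
  }
  X <- rbind(do.call(rbind, cases), do.call(rbind, controls))
  y <- c(rep(1L, n1_target), rep(0L, n0_target))
  cm <- beta; names(cm) <- paste0("X", seq_len(design$p))
  list(data = labeled_design(X, y),
       truth = truth_manifest(seq_len(design$s), cm, alpha, design$p),
       alpha = alpha)
}
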