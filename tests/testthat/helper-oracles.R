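## Independent oracles and fixture builders shared across test files.

## Literal term-by-term evaluation of the aggregate rank score:
## Rank(X_i) = M^-1 sum_h sum_j h * I(R_ij = h) * I(|B_ij| > 0),
## with within-fit ranks computed via base rank() (ties.method = "first"
## on (|value|, index) ordering) -- an independent path from the package's
## order()-assignment implementation.
literal_rank_oracle <- function(B, tol = 1e-10) {
  M <- nrow(B); p <- ncol(B)
  scores <- numeric(p)
  for (i in seq_len(p)) {
    acc <- 0
    for (j in seq_len(M)) {
      a <- abs(B[j, ])
      a[a < tol] <- 0
      R <- rank(a, ties.method = "first")
      for (h in seq_len(p)) {
        acc <- acc + h * (R[i] == h) * (a[i] > 0)
      }
    }
    scores[i] <- acc / M
  }
  scores
}

## Exhaustive single mean-changepoint: minimize pooled within-segment SSE
## over every split, computing each segment SSE directly from its mean.
changepoint_oracle <- function(scores) {
  v <- length(scores)
  sse <- function(x) sum((x - mean(x))^2)
  total <- vapply(seq_len(v - 1L), function(t)
    sse(scores[1:t]) + sse(scores[(t + 1):v]), numeric(1))
  list(tau = which.min(total), sse = min(total))
}

## Pearson correlation of two Bernoulli(1/2) indicators thresholded from a
## bivariate normal with latent correlation rho (closed-form orthant mass).
binary_corr_oracle <- function(rho) {
  p11 <- 0.25 + asin(rho) / (2 * pi)
  (p11 - 0.25) / 0.25
}

## P(two 4-category nominal clusters agree) when each is a latent normal
## (pairwise correlation rho) cut at the quartile thresholds; numeric
## integration of the conditional-normal cell mass.
nominal_agreement_oracle <- function(rho) {
  cuts <- c(-Inf, qnorm(c(0.25, 0.5, 0.75)), Inf)
  s <- sqrt(1 - rho^2)
  total <- 0
  for (k in 1:4) {
    f <- function(z) dnorm(z) * (pnorm((cuts[k + 1] - rho * z) / s) -
                                   pnorm((cuts[k] - rho * z) / s))
    total <- total + integrate(f, cuts[k], cuts[k + 1])$value
  }
  total
}

## Tiny strongly-identified imbalanced dataset for pipeline smoke tests:
## p covariates, the first `s` carry strong effects.
make_toy_imbalanced <- function(n = 3000, p = 10, s = 3, prevalence = 0.1,
                                seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  colnames(X) <- paste0("X", seq_len(p))
  beta <- c(rep(3, s), rep(0, p - s))
  alpha <- uniroot(function(a) mean(plogis(a + X %*% beta)) - prevalence,
                   c(-30, 10))$root
  y <- rbinom(n, 1, plogis(alpha + X %*% beta))
  ## ensure both classes present at test sizes
  if (sum(y) < 10) y[1:10] <- 1L
  list(data = labeled_design(X, y),
       truth = truth_manifest(seq_len(s), stats::setNames(beta, colnames(X)),
                              alpha, p))
}

## Balanced two-class design with known signal for fitting tests.
make_balanced_toy <- function(n = 400, p = 6, s = 3, beta_mag = 2.5, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  colnames(X) <- paste0("X", seq_len(p))
  beta <- c(rep(beta_mag, s), rep(0, p - s))
  y <- rbinom(n, 1, plogis(-beta_mag * s / 2 + X %*% beta))
  labeled_design(X, y)
}
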