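test_that("compute_full_size reproduces the published size grid and rejects bad input", {
  ## n = (n_b/2) * (1 + I) for every (n_b, I) combination of the experiment
  expected <- rbind(
    c(1000, 25500, 50500, 500500),
    c(2000, 51000, 101000, 1001000),
    c(3000, 76500, 151500, 1501500),
    c(4000, 102000, 202000, 2002000),
    c(5000, 127500, 252500, 2502500))
  I_values <- c(50, 100, 1000)
  for (r in seq_len(nrow(expected)))
    for (k in seq_along(I_values))
      expect_identical(compute_full_size(expected[r, 1], I_values[k]),
                       expected[r, k + 1])
  expect_identical(compute_full_size(800, 1), 800)   # already balanced
  expect_error(compute_full_size(999, 50), class = "svrs_invalid_argument")
  expect_error(compute_full_size(1000, 0), class = "svrs_invalid_argument")
})

test_that("logistic_squash is the standard logistic map", {
  expect_equal(logistic_squash(0), 0.5)
  expect_equal(logistic_squash(log(3)), 0.75)
  z <- c(-5, -0.3, 0, 2, 40)
  expect_equal(logistic_squash(z) + logistic_squash(-z), rep(1, length(z)))
  expect_true(all(diff(logistic_squash(seq(-10, 10, 0.5))) > 0))
  expect_equal(logistic_squash(c(-1e6, 1e6)), c(0, 1))
})

test_that("norta_binary marginals and dependence match the latent-normal oracle", {
  n <- 2e5
  Xc <- norta_binary(n, 3, marginal_p = 0.5, latent_corr = 0.8, seed = 11)
  expect_true(all(Xc %in% c(0, 1)))
  expect_equal(colMeans(Xc), rep(0.5, 3), tolerance = 0.01)
  emp <- cor(Xc)[upper.tri(diag(3))]
  expect_equal(emp, rep(binary_corr_oracle(0.8), 3), tolerance = 0.012)

  X0 <- norta_binary(5e4, 3, 0.5, latent_corr = 0, seed = 12)
  expect_lt(max(abs(cor(X0)[upper.tri(diag(3))])), 0.02)

  expect_error(norta_binary(10, 2, 0.5, latent_corr = 1, seed = 1),
               class = "svrs_invalid_argument")
  expect_error(norta_binary(10, 2, 1.2, 0.5, seed = 1),
               class = "svrs_invalid_argument")
})

test_that("norta_nominal_clusters gives partition-of-unity dummies with oracle-level agreement", {
  n <- 1e5
  nom <- norta_nominal_clusters(n, 3, latent_corr = 0.8, seed = 21)
  for (D in nom$dummies) {
    expect_equal(rowSums(D), rep(1, n))
    expect_equal(colMeans(D), rep(0.25, 4), tolerance = 0.01)
  }
  ## probability that clusters 1 and 2 land in the same category
  cat1 <- max.col(nom$dummies[[1]])
  cat2 <- max.col(nom$dummies[[2]])
  expect_equal(mean(cat1 == cat2), nominal_agreement_oracle(0.8),
               tolerance = 0.01)
  ## independence limit: agreement probability 1/4
  nom0 <- norta_nominal_clusters(5e4, 3, latent_corr = 0, seed = 22)
  expect_equal(mean(max.col(nom0$dummies[[1]]) == max.col(nom0$dummies[[2]])),
               0.25, tolerance = 0.01)
  expect_error(norta_nominal_clusters(10, 5, 0.5, seed = 1),
               class = "svrs_invalid_argument")
})

test_that("simulate_covariates follows each model recipe", {
  n <- 4e4
  d12 <- sim_design("UNCOR-12", 50, 1000, seed = 1)
  X <- simulate_covariates(d12, n, seed = 31)
  expect_identical(dim(X), c(as.integer(n), 100L))
  expect_true(all(X >= 0 & X <= 1))
  expect_true(all(X[, 1:6] %in% c(0, 1)))
  ## Unif(0,1) noise block moments
  expect_equal(mean(X[, 19:100]), 0.5, tolerance = 0.005)
  expect_equal(mean(apply(X[, 19:28], 2, var)), 1 / 12, tolerance = 0.005)
  ## independence of signal block
  expect_lt(max(abs(cor(X[, 7:12])[upper.tri(diag(6))])), 0.03)

  dc <- sim_design("COR-12", 50, 1000, seed = 1)
  Xc <- simulate_covariates(dc, n, seed = 32)
  ## squashed equicorrelated Gaussians: positive, near-equal pairwise corr
  cc <- cor(Xc[, 7:12])[upper.tri(diag(6))]
  expect_true(all(cc > 0.7))
  expect_lt(max(cc) - min(cc), 0.05)
  ## noise cluster 3 dummies correlate with signal cluster 1 dummies
  expect_gt(cor(Xc[, 1], Xc[, 13]), 0.3)
  ## but the separate binary block is independent of the nominal clusters
  ## and of the Gaussian block (regression test: distinct latent streams)
  expect_lt(max(abs(cor(Xc[, 16:18], Xc[, c(1:15, 19:25)]))), 0.03)
  expect_gt(min(cor(Xc[, 16:18])[upper.tri(diag(3))]), 0.5)

  dc24 <- sim_design("COR-24", 50, 1000, seed = 1)
  X24 <- simulate_covariates(dc24, n, seed = 33)
  expect_identical(dim(X24), c(as.integer(n), 200L))
  ## noise binary block correlated with signal binary block (one latent block)
  expect_gt(cor(X24[, 7], X24[, 31]), 0.4)
  expect_gt(min(cor(X24[, 13:24])[upper.tri(diag(12))]), 0.7)

  expect_error(simulate_covariates(d12, 0, seed = 1),
               class = "svrs_invalid_argument")
})

test_that("equicorrelated Gaussian block has latent correlation near 0.8", {
  n <- 1e5
  dc <- sim_design("COR-12", 50, 1000, seed = 1)
  Xc <- simulate_covariates(dc, n, seed = 41)
  latent <- qlogis(Xc[, 7:12])   # invert the squash to recover the normals
  emp <- cor(latent)[upper.tri(diag(6))]
  expect_equal(emp, rep(0.8, 15), tolerance = 0.02)
})

test_that("calibrate_intercept hits closed forms and is monotone in the target", {
  ## zero-coefficient design: alpha must equal the logit of the target
  d <- sim_design("UNCOR-12", 50, 1000, seed = 1)
  d$signal_coefficients <- rep(0, 12)
  a <- calibrate_intercept(d, 1 / 51, mc_size = 1e4, seed = 5)
  expect_equal(a, qlogis(1 / 51), tolerance = 1e-4)

  d2 <- sim_design("UNCOR-12", 50, 1000, seed = 1)
  a50 <- calibrate_intercept(d2, 1 / 51, mc_size = 1e5, seed = 5)
  a1000 <- calibrate_intercept(d2, 1 / 1001, mc_size = 1e5, seed = 5)
  expect_lt(a1000, a50)

  ## self-consistency: prevalence simulated at the calibrated alpha
  set.seed(77)
  X <- simulate_covariates(d2, 2e5, seed = 6)
  beta <- c(d2$signal_coefficients, rep(0, 88))
  pbar <- mean(plogis(a50 + X %*% beta))
  se <- sd(plogis(a50 + X %*% beta)) / sqrt(2e5)
  expect_lt(abs(pbar - 1 / 51), 3 * se + 2e-4)

  expect_error(calibrate_intercept(d2, 0.7, seed = 1),
               class = "svrs_invalid_argument")
})

test_that("simulate_dataset delivers exact class counts, reproducibly", {
  des <- sim_design("UNCOR-12", 9, 300, seed = 123)
  sim <- simulate_dataset(des)
  expect_identical(sum(sim$data$y == 1L), 150L)
  expect_identical(sum(sim$data$y == 0L), 9L * 150L)
  expect_identical(nrow(sim$data$X), as.integer(compute_full_size(300, 9)))
  ## truth manifest partitions covariates
  expect_identical(sort(c(sim$truth$signal_indices, sim$truth$noise_indices)),
                   1:100)
  expect_identical(length(sim$truth$signal_indices), 12L)

  sim2 <- simulate_dataset(des)
  expect_identical(sim$data, sim2$data)
  expect_identical(sim$alpha, sim2$alpha)

  ## strong positive coefficient => higher covariate mean among cases
  x12 <- sim$data$X[, 12]
  expect_gt(mean(x12[sim$data$y == 1]), mean(x12[sim$data$y == 0]))
})

test_that("sim_design validates its fields", {
  expect_error(sim_design("UNCOR-13", 50, 1000, 1))
  expect_error(sim_design("UNCOR-12", 50, 999, 1), class = "svrs_invalid_argument")
  expect_error(sim_design("UNCOR-12", 0, 1000, 1), class = "svrs_invalid_argument")
  expect_error(sim_design("UNCOR-12", 50, 1000, 1, latent_corr = 1),
               class = "svrs_invalid_argument")
  d <- sim_design("COR-24", 100, 2000, 1)
  expect_identical(d$p, 200L)
  expect_identical(d$s, 24L)
  expect_identical(length(d$signal_coefficients), 24L)
})

test_that("dataset and truth round-trip through CSV/JSON", {
  toy <- make_toy_imbalanced(n = 500, p = 4, s = 2, seed = 9)
  csv <- tempfile(fileext = ".csv")
  write_labeled_csv(toy$data, csv)
  back <- read_labeled_csv(csv)
  expect_equal(back$X, toy$data$X, tolerance = 1e-12)
  expect_identical(back$y, toy$data$y)

  js <- tempfile(fileext = ".json")
  write_truth_json(toy$truth, js)
  tr <- read_truth_json(js)
  expect_identical(tr$signal_indices, toy$truth$signal_indices)
  expect_equal(tr$coefficient_map, toy$truth$coefficient_map)
})
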