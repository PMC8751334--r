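test_that("all generators are bit-reproducible under seed", {
  expect_identical(simulate_planted_rank_one(seed = 1)$matrix,
                   simulate_planted_rank_one(seed = 1)$matrix)
  expect_identical(simulate_groups(n_genes = 100, n_cells = 50, seed = 2)$counts,
                   simulate_groups(n_genes = 100, n_cells = 50, seed = 2)$counts)
  expect_identical(simulate_differentiation_path(seed = 3)$matrix,
                   simulate_differentiation_path(seed = 3)$matrix)
  expect_identical(simulate_multiplicative(seed = 4)$matrix,
                   simulate_multiplicative(seed = 4)$matrix)
  x <- standardized_noise(100, 40, seed = 5)
  expect_identical(add_planted_signal(x, 2, seed = 6)$matrix,
                   add_planted_signal(x, 2, seed = 6)$matrix)
  expect_identical(add_planted_signal(x, 0, seed = 6)$matrix, x)
})

test_that("planted signals land where the forward map predicts", {
  c0 <- 201 / 350
  lead <- vapply(1:50, function(s) {
    scaled_svd(simulate_planted_rank_one(theta = 2, seed = 200 + s)$matrix)$gamma[1]
  }, numeric(1))
  expect_lt(abs(mean(lead) - gamma_additive(2, c0)), 0.05)
  # theta recovery within 3 percent for theta in {2, 5}
  expect_lt(abs(theta_additive(mean(lead), c0) - 2) / 2, 0.03)
  lead5 <- vapply(1:20, function(s) {
    scaled_svd(simulate_planted_rank_one(theta = 5, seed = 300 + s)$matrix)$gamma[1]
  }, numeric(1))
  expect_lt(abs(theta_additive(mean(lead5), c0) - 5) / 5, 0.03)
})

test_that("Poisson noise behaves like Gaussian noise after preprocessing", {
  ok <- vapply(1:25, function(s) {
    sim <- simulate_planted_rank_one(theta = 2, noise = "poisson",
                                     seed = 400 + s)
    x <- standardize_expression(sim$matrix)
    sv <- scaled_svd(x)
    mp <- mp_model(350, 201)
    ks_bulk_test(sv, mp, seed = s) > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.85)
})

test_that("group simulator respects proportions and the null case", {
  sim <- simulate_groups(n_genes = 300, n_cells = 1000, n_groups = 2,
                         group_prob = c(0.3, 0.7), de_prob = 0.2, seed = 7)
  sizes <- table(sim$labels$cluster)
  expect_equal(unname(as.integer(sizes)), c(300, 700))

  null2 <- simulate_groups(n_genes = 800, n_cells = 300, n_groups = 2,
                           de_prob = 0, seed = 8)
  fit <- phiclust(null2$counts)
  expect_identical(fit$clusters$phiclust, 0)
})

test_that("weighted mixtures interpolate between identical and distinct", {
  src <- simulate_groups(n_genes = 1000, n_cells = 400, n_groups = 2,
                         de_prob = 0.3, seed = 9)
  proc <- preprocess_counts(src$counts)$values
  grp <- src$labels$cluster
  a <- proc[, grp == "group1"]
  b <- proc[, grp == "group2"]
  run <- function(alpha, seed) {
    mix <- simulate_weighted_mixture(a, b, alpha = alpha,
                                     n_cells_per_cluster = 100, seed = seed)
    phiclust(mix$matrix, preprocess = "standardize",
             config = phiclust_config(seed = seed))$clusters$phiclust
  }
  at_half <- mean(vapply(1:5, function(s) run(0.5, s), numeric(1)))
  at_three <- mean(vapply(1:5, function(s) run(0.75, s), numeric(1)))
  at_one <- mean(vapply(1:5, function(s) run(1, s), numeric(1)))
  expect_lt(at_half, 0.05)
  expect_lte(at_half, at_three + 0.05)
  expect_lte(at_three, at_one + 0.05)
  expect_gt(at_one, 0.5)
  expect_error(simulate_weighted_mixture(a[1:10, ], b, 0.5), "gene axis")
  expect_error(simulate_weighted_mixture(a, b, 0.5, n_cells_per_cluster = 500),
               "without replacement")
  expect_error(simulate_weighted_mixture(a, b, 1.5), "alpha")
})

test_that("multiplicative generator keeps an MP bulk and maps lambda to theta", {
  sim0 <- simulate_multiplicative(theta = 0, seed = 10)
  s0 <- scaled_svd(sim0$matrix)
  mp <- mp_model(350, 201)
  expect_lt(s0$gamma[1]^2, mp$tw_lambda_star * 1.1)

  lam <- vapply(1:15, function(s) {
    scaled_svd(simulate_multiplicative(n_genes = 1000, n_cells = 500,
                                       theta = 8, seed = 500 + s)$matrix)$gamma[1]^2
  }, numeric(1))
  pred <- lambda_multiplicative(8, 0.5)
  expect_lt(abs(mean(lam) - pred) / pred, 0.05)
  # for large planted theta the scaled leading eigenvalue approaches theta
  lam50 <- vapply(1:6, function(s) {
    scaled_svd(simulate_multiplicative(n_genes = 1000, n_cells = 500,
                                       theta = 50, seed = 520 + s)$matrix)$gamma[1]^2
  }, numeric(1))
  expect_lt(abs(mean(lam50) - 50) / 50, 0.1)

  ok <- vapply(1:10, function(s) {
    sim <- simulate_multiplicative(theta = 5, seed = 600 + s)
    ks_bulk_test(scaled_svd(sim$matrix), mp, seed = s) > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("differentiation path is pure noise at zero gradient", {
  sim <- simulate_differentiation_path(n_genes = 500, n_cells = 200,
                                       gradient_strength = 0, seed = 11)
  fit <- phiclust(sim$matrix, preprocess = "none")
  expect_identical(fit$clusters$phiclust, 0)
  expect_identical(nrow(sim$pseudotime), 200L)
})
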