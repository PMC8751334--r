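test_that("ARI matches brute-force pair counting and its identities", {
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 1, 2, 2)  # the 2x2 contingency {2,1;1,2}
  expect_equal(ari(a, b), ari_bruteforce(a, b), tolerance = 1e-12)
  expect_equal(ari(a, a), 1)
  expect_equal(ari(a, rep(1, 6)), 0)
  withr::with_seed(1, {
    for (i in 1:5) {
      x <- sample(1:3, 30, replace = TRUE)
      y <- sample(1:3, 30, replace = TRUE)
      expect_equal(ari(x, y), ari_bruteforce(x, y), tolerance = 1e-12)
      expect_equal(ari(x, y), ari(y, x))
      perm <- c("c", "a", "b")[y]
      expect_equal(ari(x, perm), ari(x, y))
    }
  })
  expect_error(ari(a, b[-1]), "mismatch")
})

test_that("silhouette matches the hand oracle and its limits", {
  x <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  lab <- rep(c("A", "B"), each = 3)
  expect_equal(tsil(x, lab), silhouette_bruteforce(x, lab), tolerance = 1e-10)
  expect_gt(tsil(x, lab), 0.95)
  inter <- c(0, 1, 2, 3, 4, 5)
  expect_lt(abs(tsil(inter, rep(c("A", "B"), 3))), 0.4)
  expect_warning(v <- tsil(x, rep("A", 6)), "undefined")
  expect_true(is.na(v))
})

test_that("Bayes classifier is exact when separable, degenerate on noise", {
  sim <- simulate_planted_rank_one(theta = 8, seed = 700)
  s <- scaled_svd(sim$matrix)
  mp <- mp_model(350, 201)
  truth <- sim$labels$cluster
  pred <- bayes_classify(s, mp, truth)
  expect_equal(ari(pred, truth), 1)

  x0 <- standardized_noise(350, 201, seed = 701)
  tm <- truth_metrics(x0, rep(c("A", "B"), length.out = 201), seed = 1)
  expect_identical(tm$tari, 0)
  expect_identical(tm$n_components_used, 0L)
})

test_that("empirical misclassification matches the closed-form Bayes error", {
  mu <- 1  # two unit-variance Gaussians at +/- mu: Bayes error = pnorm(-mu)
  n <- 1e4
  coords <- withr::with_seed(11, c(rnorm(n / 2, -mu), rnorm(n / 2, mu)))
  truth <- rep(c("lo", "hi"), each = n / 2)
  fake <- structure(list(
    gamma = c(3, rep(0.5, 9)),
    v_cell = cbind(coords, matrix(rnorm(n * 9), n, 9)),
    u_gene = NULL, c = 0.5, n_genes = 2 * n, n_cells = n,
    n_major = 2 * n, transposed = FALSE
  ), class = "scaled_svd")
  mp <- mp_model(2 * n, n)
  pred <- bayes_classify(fake, mp, truth)
  err <- mean(pred != truth)
  expect_lt(abs(err - pnorm(-mu)), 0.02)
})

test_that("k-means baseline is seeded and solves separated blobs", {
  pts <- withr::with_seed(21, rbind(
    matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 6), 50, 2)
  ))
  truth <- rep(1:2, each = 50)
  lab <- kmeans_baseline(pts, k = 2, seed = 5)
  expect_equal(ari(lab, truth), 1)
  expect_identical(lab, kmeans_baseline(pts, k = 2, seed = 5))
  expect_error(kmeans_baseline(pts, k = 200, seed = 1), "exceeds")
  expect_error(kmeans_baseline(pts, k = 1, seed = 1), ">= 2")
})
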