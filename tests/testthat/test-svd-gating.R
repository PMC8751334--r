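test_that("scaled SVD recovers a hand-computable diagonal spectrum", {
  m <- rbind(diag(c(sqrt(3) * 2, sqrt(3) * 1)), 0)
  s <- scaled_svd(m)
  expect_equal(s$gamma, c(2, 1), tolerance = 1e-12)
  expect_equal(s$c, 2 / 3)
})

test_that("reconstruction, scale-freeness and the sign convention hold", {
  x <- standardized_noise(80, 50, seed = 41)
  s <- scaled_svd(x)
  expect_lt(norm(reconstruct_svd(s) - x, "F") / norm(x, "F"), 1e-6)
  expect_lt(max(abs(crossprod(s$v_cell) - diag(50))), 1e-8)
  expect_lt(max(abs(crossprod(s$u_gene) - diag(50))), 1e-8)
  s3 <- scaled_svd(3 * x)
  expect_equal(s3$gamma, 3 * s$gamma, tolerance = 1e-10)
  expect_equal(s3$v_cell, s$v_cell, tolerance = 1e-8)
  # largest-magnitude entry of every cell vector is positive
  picks <- apply(s$v_cell, 2, function(v) v[which.max(abs(v))])
  expect_true(all(picks > 0))
  x[1, 1] <- NaN
  expect_error(scaled_svd(x), "non-finite")
})

test_that("a wide matrix is transposed internally with roles exchanged", {
  x <- standardized_noise(80, 50, seed = 42)
  s <- scaled_svd(x)
  st <- scaled_svd(t(x))
  expect_true(st$transposed)
  expect_equal(st$gamma, s$gamma, tolerance = 1e-10)
  expect_equal(st$c, s$c)
  expect_equal(dim(st$v_cell), c(80, 50)) # cells of t(x) are genes of x
})

test_that("gating finds the planted component and nothing in noise", {
  sim <- simulate_planted_rank_one(theta = 5, seed = 51)
  s <- scaled_svd(sim$matrix)
  mp <- mp_model(350, 201)
  gate <- significant_components(s, mp)
  expect_identical(gate$index[gate$significant], 1L)
  expect_identical(sum(gate$significant), 1L)

  s0 <- scaled_svd(standardized_noise(350, 201, seed = 52))
  gate0 <- significant_components(s0, mp)
  expect_identical(sum(gate0$significant), 0L)
})

test_that("a TW-passing component with a normal singular vector is gated out", {
  # multiplicative planted signal: the outlying eigenvalue is real, but its
  # cell-singular vector is a rotated noise direction with normal entries
  sim <- simulate_multiplicative(n_genes = 600, n_cells = 300, theta = 8,
                                 seed = 53)
  s <- scaled_svd(sim$matrix)
  mp <- mp_model(600, 300)
  gate <- significant_components(s, mp)
  expect_gt(nrow(gate), 0)            # TW picks it up
  expect_identical(sum(gate$significant), 0L) # normality gate drops it
})
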