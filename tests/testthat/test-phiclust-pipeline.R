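test_that("planted signal recovers the closed-form angle; pure noise gives 0", {
  c0 <- 201 / 350
  vals <- vapply(1:20, function(s) {
    sim <- simulate_planted_rank_one(theta = 5, seed = 100 + s)
    phiclust(sim$matrix, preprocess = "none",
             config = phiclust_config(seed = s))$clusters$phiclust
  }, numeric(1))
  expect_lt(abs(mean(vals) - as.numeric(phi_cell(5, c0))), 0.02)

  sim0 <- simulate_planted_rank_one(theta = 0, seed = 121)
  fit0 <- phiclust(sim0$matrix, preprocess = "none")
  expect_identical(fit0$clusters$phiclust, 0)
  expect_identical(fit0$clusters$n_significant, 0L)
})

test_that("phiclust is invariant under gene and cell relabeling", {
  sim <- simulate_planted_rank_one(theta = 3, seed = 131)
  f1 <- phiclust(sim$matrix, preprocess = "none")
  gi <- withr::with_seed(1, sample(nrow(sim$matrix)))
  ci <- withr::with_seed(2, sample(ncol(sim$matrix)))
  f2 <- phiclust(sim$matrix[gi, ci], preprocess = "none")
  expect_equal(f2$clusters$phiclust, f1$clusters$phiclust, tolerance = 1e-8)
  expect_equal(f2$clusters$g_phiclust, f1$clusters$g_phiclust, tolerance = 1e-8)
})

test_that("per-cluster results follow the labels and small clusters error", {
  sim <- simulate_groups(n_genes = 400, n_cells = 160, n_groups = 2,
                         de_prob = 0.3, seed = 141)
  fit <- suppressWarnings(
    phiclust(sim$counts, labels = sim$labels)
  )
  expect_identical(sort(fit$clusters$cluster_id), c("group1", "group2"))
  expect_identical(fit$clusters$bulk_ks_p_adj,
                   p.adjust(fit$clusters$bulk_ks_p, "BH"))
  bad <- sim$labels
  bad$cluster[1:5] <- "tiny"
  bad <- bad[bad$cluster == "tiny" | bad$cluster == "group1", ]
  expect_error(suppressWarnings(phiclust(sim$counts, labels = bad)),
               "fewer than 10 cells")
})

test_that("uncertainty is zero without components, deterministic, positive with", {
  sim0 <- simulate_planted_rank_one(theta = 0, seed = 151)
  f0 <- phiclust(sim0$matrix, preprocess = "none", uncertainty = TRUE)
  expect_identical(f0$clusters$sigma_plus, 0)
  expect_identical(f0$clusters$sigma_minus, 0)

  sim <- simulate_planted_rank_one(theta = 5, seed = 152)
  cfg <- phiclust_config(n_boot = 25, seed = 9)
  f1 <- phiclust(sim$matrix, preprocess = "none", config = cfg,
                 uncertainty = TRUE)
  f2 <- phiclust(sim$matrix, preprocess = "none", config = cfg,
                 uncertainty = TRUE)
  expect_identical(f1$clusters$sigma_plus, f2$clusters$sigma_plus)
  expect_identical(f1$clusters$sigma_minus, f2$clusters$sigma_minus)
  expect_gt(f1$clusters$sigma_plus + f1$clusters$sigma_minus, 0)
  # resampled spread brackets the point estimate
  expect_lt(f1$clusters$phiclust - 3 * f1$clusters$sigma_minus, 1)
})

test_that("variance-driving genes concentrate in the planted support", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_planted_rank_one(theta = 5, seed = 160 + s)
    fit <- phiclust(sim$matrix, preprocess = "none")
    top <- variance_driving_genes(fit, top_n = 20)
    idx <- match(top$gene_id, rownames(sim$matrix))
    # align the measured component with the planted gene vector
    u_hat <- fit$svds[["all"]]$u_gene[, top$component_index[1]]
    aligned <- sign(sum(u_hat * sim$u))
    pos <- top$loading * aligned > 0
    mean(idx[pos] <= 200)  # planted positive support is genes 1..200
  }, numeric(1))
  expect_gte(mean(hits), 0.9)

  sim <- simulate_planted_rank_one(theta = 5, seed = 171)
  fit <- phiclust(sim$matrix, preprocess = "none")
  expect_identical(nrow(variance_driving_genes(fit, top_n = 0)), 0L)
  expect_error(variance_driving_genes(fit, component_index = 50),
               "not a significant component")
})

test_that("a pseudotime covariate absorbs a differentiation gradient", {
  sim <- simulate_differentiation_path(gradient_strength = 3, seed = 181)
  f_raw <- phiclust(sim$matrix, preprocess = "none")
  expect_gt(f_raw$clusters$phiclust, 0.5)
  f_cov <- phiclust(sim$matrix, covariates = sim$pseudotime,
                    preprocess = "none")
  expect_identical(f_cov$clusters$phiclust, 0)
})

test_that("tidy, glance and the plots expose the fit", {
  sim <- simulate_planted_rank_one(theta = 5, seed = 191)
  fit <- phiclust(sim$matrix, preprocess = "none")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$phiclust, fit$clusters$phiclust)
  gl <- glance(fit)
  expect_identical(gl$n_clusterable, 1L)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_spectrum(fit), "ggplot")
})
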