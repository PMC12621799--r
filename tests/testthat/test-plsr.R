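test_that("z-scoring gives zero-mean unit-variance columns and drops constants", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- zscore_block(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)
  # idempotence
  expect_equal(zscore_block(z), z, tolerance = 1e-12, ignore_attr = TRUE)
  m2 <- cbind(a = c(1, 2, 3), const = c(5, 5, 5))
  expect_warning(z2 <- zscore_block(m2), "zero-variance")
  expect_identical(colnames(z2), "a")
  expect_error(zscore_block(matrix(1, 1, 3)), "at least 2")
})

test_that("a noise-free linear response is captured by one component", {
  set.seed(1)
  # centred orthogonal predictors: the first covariance direction is exact
  X <- svd(scale(matrix(rnorm(8 * 5), 8, 5), scale = FALSE))$u[, 1:5] * 2
  Y <- X[, 1L, drop = FALSE]
  fit <- fit_plsr(X, Y, n_components = 1L)
  expect_gt(fit$r2y_cum[1L], 0.999)
  # correlated predictors still reach R2 ~ 1 at full rank
  Xr <- matrix(rnorm(8 * 5), 8, 5)
  fitr <- fit_plsr(Xr, Xr[, 1L, drop = FALSE], n_components = 5L)
  expect_gt(fitr$r2y_cum[5L], 0.999)
  # planted rank-1 structure: one component captures both blocks
  t1 <- rnorm(8)
  X1 <- t1 %*% t(rnorm(6))
  Y1 <- t1 %*% t(rnorm(3))
  fit1 <- suppressWarnings(fit_plsr(X1, Y1, n_components = 2L))
  expect_gt(fit1$r2x[1L], 0.99)
  expect_gt(fit1$r2y[1L], 0.99)
  expect_error(fit_plsr(matrix(0, 6, 4), matrix(rnorm(12), 6, 2), 2),
               "degenerate")
})

test_that("SIMPLS predictions agree with an independent NIPALS fit", {
  set.seed(3)
  X <- matrix(rnorm(30), 6, 5)
  Y <- matrix(rnorm(12), 6, 2)
  # full-rank fits reproduce the same projection
  fit <- fit_plsr(X, Y, n_components = 5L)
  nip <- nipals_pls(X, Y, n_components = 5L)
  expect_lt(max(abs(predict(fit, X) - nipals_predict(nip, X))), 1e-6)
  # and the leading component is algorithm-independent
  fit1 <- fit_plsr(X, Y, n_components = 1L)
  nip1 <- nipals_pls(X, Y, n_components = 1L)
  expect_lt(max(abs(predict(fit1, X) - nipals_predict(nip1, X))), 1e-8)
})

test_that("fitted models satisfy the latent-variable invariants", {
  for (seed in 1:4) {
    b <- gen_omics_blocks(omics_config(n_probes = 40L, noise_sigma = 0.1,
                                       seed = seed))
    Xz <- zscore_block(b$X)
    Yz <- zscore_block(b$Y)
    fit <- fit_plsr(Xz, Yz, n_components = 5L)
    # cumulative R2 non-decreasing and bounded by 1
    expect_true(all(diff(fit$r2y_cum) >= -1e-12))
    expect_lte(max(fit$r2y_cum), 1 + 1e-9)
    expect_lte(max(fit$r2x_cum), 1 + 1e-9)
    # orthonormal score columns
    gram <- crossprod(fit$scores)
    expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
    # Q2 never beats in-sample R2
    q2 <- loo_q2(Xz, Yz, n_components = 5L)
    expect_true(all(q2$q2 <= fit$r2y_cum[seq_len(nrow(q2))] + 1e-9))
  }
})

test_that("leave-one-out Q2 separates signal from permuted null", {
  b <- gen_omics_blocks(omics_config(noise_sigma = 0.05, seed = 12L))
  Xz <- zscore_block(b$X)
  Yz <- zscore_block(b$Y)
  q2 <- loo_q2(Xz, Yz, n_components = 2L)
  expect_gt(q2$q2[2L], 0.8)
  set.seed(99)
  null_q2 <- replicate(20L, {
    loo_q2(Xz, Yz[sample(nrow(Yz)), , drop = FALSE], n_components = 2L)$q2[2L]
  })
  expect_lte(median(null_q2), 0)
  expect_error(loo_q2(Xz[1:2, ], Yz[1:2, ]), "at least 3")
})

test_that("the 2-component fit recovers the planted loading subspace", {
  for (seed in 1:3) {
    b <- gen_omics_blocks(omics_config(noise_sigma = 0.05, seed = seed))
    fit <- fit_plsr(b$X, b$Y, n_components = 2L)
    expect_lt(max_principal_angle(fit$x_loadings, b$x_loadings), 10)
  }
})

test_that("more noise does not improve predictive Q2", {
  mean_q2 <- function(sigma) {
    mean(vapply(1:10, function(s) {
      b <- gen_omics_blocks(omics_config(n_probes = 40L, noise_sigma = sigma,
                                         seed = s))
      loo_q2(b$X, b$Y, n_components = 2L)$q2[2L]
    }, numeric(1L)))
  }
  expect_gte(mean_q2(0.05), mean_q2(0.1))
})

test_that("k-means on the loading plane recovers planted separation", {
  b <- gen_omics_blocks(omics_config(n_probes = 60L, noise_sigma = 0.02,
                                     seed = 5L))
  fit <- fit_plsr(b$X, b$Y, n_components = 2L)
  # plant two clean blobs in the loading plane to make the partition known
  fake <- fit
  lab <- rep(1:2, each = 30L)
  set.seed(8)
  fake$x_loadings[, 1:2] <- cbind(ifelse(lab == 1L, -5, 5) + rnorm(60, 0, 0.1),
                                  rnorm(60, 0, 0.1))
  cl <- kmeans_loadings(fake, k = 2L, seed = 17L)
  expect_length(unique(cl$assignment), 2L)
  expect_true(all(cl$assignment %in% 1:2))
  split_lab <- split(lab, cl$assignment)
  expect_true(all(vapply(split_lab, function(g) length(unique(g)) == 1L,
                         logical(1L))))
  # determinism and the saturated-k edge
  cl2 <- kmeans_loadings(fake, k = 2L, seed = 17L)
  expect_identical(cl$assignment, cl2$assignment)
  cl_all <- kmeans_loadings(fit, k = 60L, seed = 1L)
  expect_length(unique(cl_all$assignment), 60L)
  expect_error(kmeans_loadings(fit, k = 61L), "exceeds")
})

test_that("alignment scores are cosines in the first-two-component plane", {
  model <- structure(
    list(
      n_components = 2L,
      x_loadings = matrix(c(2, 0, -3, 0, 0, -3), 3, 2, byrow = TRUE,
                          dimnames = list(c("par", "anti", "orth"), NULL)),
      y_loadings = matrix(c(1, 0), 1, 2,
                          dimnames = list("area", NULL))
    ),
    class = "plsr_model"
  )
  sc <- alignment_scores(model, "area")
  expect_equal(unname(sc["par"]), 1)
  expect_equal(unname(sc["anti"]), -1)
  expect_equal(unname(sc["orth"]), 0)
  expect_error(alignment_scores(model, "nosuch"), "unknown phenotype")
  # negating a phenotype's loading negates every alignment score
  b <- gen_omics_blocks(omics_config(n_probes = 25L, seed = 9L))
  fit <- fit_plsr(zscore_block(b$X), zscore_block(b$Y), 2L)
  neg <- fit
  neg$y_loadings["area", ] <- -neg$y_loadings["area", ]
  expect_equal(alignment_scores(neg, "area"),
               -alignment_scores(fit, "area"))
})

test_that("observed-versus-fitted R2 matches a direct correlation oracle", {
  set.seed(11)
  X <- matrix(rnorm(36), 6, 6)
  B <- matrix(rnorm(18), 6, 3)
  Y <- X %*% B
  colnames(Y) <- c("y1", "y2", "y3")
  fit <- fit_plsr(X, Y, n_components = 5L)
  r2 <- observed_vs_fitted(fit, X, Y)
  expect_true(all(r2 > 0.999))
  pred <- predict(fit, X)
  for (o in colnames(Y)) {
    expect_equal(r2[[o]], cor(Y[, o], pred[, o])^2, tolerance = 1e-10)
  }
  Yc <- cbind(Y, flat = rep(2, 6))
  fit2 <- suppressWarnings(fit_plsr(X, Yc, n_components = 3L))
  expect_warning(r2c <- observed_vs_fitted(fit2, X, Yc, "flat"), "constant")
  expect_true(is.na(r2c[["flat"]]))
})
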