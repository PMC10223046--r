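test_that("standardizer uses the population standard deviation", {
  p <- fit_standardizer(matrix(c(0, 2, 4), ncol = 1))
  expect_equal(p$mu, 2)
  expect_equal(p$sigma, sqrt(8 / 3))          # 1.63299...
  expect_equal(apply_standardizer(matrix(4, 1, 1), p)[1, 1],
               2 / sqrt(8 / 3))               # 1.22474...
  expect_equal(apply_standardizer(matrix(2, 1, 1), p)[1, 1], 0)
})

test_that("standardization is idempotent in distribution and handles sigma 0", {
  set.seed(3)
  X <- matrix(rnorm(200, mean = 5, sd = 2), 20, 10)
  X[, 4] <- 7  # constant variable
  p <- fit_standardizer(X)
  S <- apply_standardizer(X, p)
  expect_lt(max(abs(colMeans(S))), 1e-6)
  popsd <- sqrt(colMeans(sweep(S, 2, colMeans(S))^2))
  expect_equal(popsd[-4], rep(1, 9), tolerance = 1e-6)
  expect_true(all(S[, 4] == 0))
  # refitting on standardized data: mu ~ 0, sigma ~ 1
  p2 <- fit_standardizer(S[, -4])
  expect_lt(max(abs(p2$mu)), 1e-8)
  expect_equal(p2$sigma, rep(1, 9), tolerance = 1e-8)
  expect_error(apply_standardizer(X[, 1:5], p), "dimension mismatch")
  expect_error(fit_standardizer(X[integer(0), ]), "empty")
})

test_that("PCA matches an independent eigendecomposition oracle", {
  set.seed(7)
  X <- matrix(rnorm(24), 6, 4)
  k <- 4
  model <- fit_pca(X, k)
  # oracle: eigendecomposition of the covariance matrix, computed separately
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / nrow(X), symmetric = TRUE)
  expect_equal(model$explained_variance, ev$values[1:k], tolerance = 1e-8)
  # loadings orthonormal
  G <- crossprod(model$loadings)
  expect_equal(G, diag(k), tolerance = 1e-8)
  # full-rank reconstruction reproduces X
  scores <- apply_pca(X, model)
  recon <- scores %*% t(model$loadings) + rep(colMeans(X), each = nrow(X))
  expect_equal(recon, X, tolerance = 1e-8)
  # explained variance non-increasing
  expect_true(all(diff(model$explained_variance) <= 1e-12))
})

test_that("PCA handles rank-1 data, mean spectra, and k bounds", {
  # points exactly on a line through their mean: one component explains all
  t <- seq(-2, 2, length.out = 9)
  X <- cbind(1 + 2 * t, 3 - t, 0.5 * t + 4)
  m1 <- fit_pca(X, 1)
  resid <- sweep(X, 2, colMeans(X)) -
    apply_pca(X, m1) %*% t(m1$loadings)
  expect_lt(max(abs(resid)), 1e-10)
  # a row equal to the training mean scores zero
  expect_equal(drop(apply_pca(matrix(colMeans(X), 1), m1)), 0,
               tolerance = 1e-10)
  expect_error(fit_pca(X, 9), "k = 9 out of range")
  expect_error(apply_pca(X[, 1:2], m1), "dimension mismatch")
})

test_that("PCA scores are uncorrelated and residuals shrink with k", {
  set.seed(21)
  X <- matrix(rnorm(300), 30, 10) %*% diag(sqrt(10:1))
  errs <- vapply(c(2, 5, 10), function(k) {
    m <- fit_pca(X, k)
    R <- sweep(X, 2, colMeans(X)) - apply_pca(X, m) %*% t(m$loadings)
    sum(R^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  expect_lt(errs[3], 1e-8)  # k = rank
  m5 <- fit_pca(X, 5)
  S <- apply_pca(X, m5)
  cv <- crossprod(sweep(S, 2, colMeans(S))) / nrow(S)
  off <- cv - diag(diag(cv))
  expect_lt(max(abs(off)), 1e-6 * cv[1, 1])
})

test_that("systematic split reproduces the interleaved 7:3 pattern", {
  # 10 items, one stratum: indices 0..9, test when i mod 10 >= 7
  g <- tiny_grid(4)
  ds10 <- spectra_dataset(matrix(runif(40), 10, 4),
                          data.frame(sample_id = letters[1:10],
                                     product_class = 1,
                                     physical_state = "thawed"), g)
  sp <- systematic_split(ds10)
  expect_equal(n_spectra(sp$train), 7L)
  expect_equal(n_spectra(sp$test), 3L)
  expect_equal(sp$test$meta$sample_id, c("h", "i", "j"))
  # 20 items: brute-force enumeration of the documented rule
  ds20 <- spectra_dataset(matrix(runif(80), 20, 4),
                          data.frame(sample_id = sprintf("s%02d", 1:20),
                                     product_class = 1,
                                     physical_state = "thawed"), g)
  sp20 <- systematic_split(ds20)
  expect_equal(n_spectra(sp20$train), 14L)
  i0 <- 0:19
  expect_equal(sp20$test$meta$sample_id,
               sprintf("s%02d", which((i0 %% 10) >= 7)))
})

test_that("systematic split stratifies, is deterministic, and errors on tiny strata", {
  ds <- small_synth(seed = 5, n_samples = 2, n_rep = 10, end_nm = 360)
  sp1 <- systematic_split(ds)
  sp2 <- systematic_split(ds)
  expect_identical(sp1$train$meta, sp2$train$meta)
  expect_equal(n_spectra(sp1$train) + n_spectra(sp1$test), n_spectra(ds))
  # each class x state stratum of 20 splits 14/6
  tr_tab <- table(sp1$train$meta$product_class, sp1$train$meta$physical_state)
  expect_true(all(tr_tab == 14))
  expect_error(split_spec(train_fraction = 0),
               "strictly between")
  # rows 1 and 11 are one frozen and one thawed replicate: strata of size 1
  one <- subset_spectra(ds, c(1, 11))
  expect_error(systematic_split(one), "at least 2")
})
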