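test_that("min-max rescaling matches its defining formula", {
  p <- fit_minmax(c(0, 5, 10), eps = 1e-8)
  expect_equal(apply_norm(c(0, 5, 10), p), c(0, 0.5, 1), tolerance = 1e-7)
  # constant column is eps-guarded to zero
  pc <- fit_minmax(c(4, 4, 4))
  expect_equal(apply_norm(c(4, 4, 4), pc), c(0, 0, 0))
  # frozen parameters applied to an unseen value
  p2 <- fit_minmax(c(2, 4), eps = 1e-10)
  expect_equal(apply_norm(3, p2), 0.5, tolerance = 1e-7)
  # no clipping outside the training range
  expect_gt(apply_norm(5, p2), 1)
  expect_lt(apply_norm(1, p2), 0)
})

test_that("z-scoring centers and unit-scales with the N-1 variance", {
  p <- fit_zscore(c(1, 3), eps = 1e-12)
  expect_equal(apply_norm(c(1, 3), p), c(-1, 1) / sqrt(2), tolerance = 1e-3)
  x <- rnorm(50, mean = 7, sd = 3)
  px <- fit_zscore(x)
  z <- apply_norm(x, px)
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-6)
  # constant column maps to zero; single value is an error
  expect_equal(apply_norm(c(2, 2), fit_zscore(c(2, 2))), c(0, 0))
  expect_error(fit_zscore(3), "at least 2")
  expect_error(fit_minmax(c(1, Inf)), "non-finite")
})

test_that("dataset normalization is per-block, structure-preserving", {
  ds <- make_toy_dataset(n_per_class = 15)
  res <- normalize_dataset(ds)
  img <- res$dataset$X[, res$dataset$blocks$imaging]
  expect_true(all(img >= 0 & img < 1))
  snp <- res$dataset$X[, res$dataset$blocks$snp]
  expect_true(all(abs(colMeans(snp)) < 1e-10))
  expect_identical(res$dataset$blocks, ds$blocks)
  expect_identical(res$dataset$y, ds$y)
  expect_identical(res$dataset$feature_names, ds$feature_names)
  expect_error(normalize_dataset(ds, schemes = c(imaging = "minmax")),
               "no normalization scheme")
  expect_error(normalize_dataset(ds, schemes = c(imaging = "rank",
                                                 snp = "zscore")),
               "unknown normalization scheme")
})

test_that("frozen fold-train parameters transform held-out data without leakage", {
  ds <- make_toy_dataset(n_per_class = 20, seed = 8)
  train <- mm_subset_samples(ds, c(1:15, 21:35))
  test <- mm_subset_samples(ds, c(16:20, 36:40))
  fitres <- normalize_dataset(train)
  applied <- normalize_dataset(test, params = fitres$params)
  # transform must depend only on train statistics
  p1 <- fitres$params[[1]]
  expect_equal(applied$dataset$X[, 1],
               (test$X[, 1] - p1$min) / (p1$max - p1$min + p1$eps))
  # test values may legitimately fall outside [0,1)
  expect_identical(applied$dataset$sample_ids, test$sample_ids)
})

test_that("normalization is per-feature and monotone", {
  ds <- make_toy_dataset(n_per_class = 12, seed = 5)
  res <- normalize_dataset(ds)
  perm <- sample(nrow(ds$X))
  res_perm <- normalize_dataset(mm_subset_samples(ds, perm))
  expect_equal(res_perm$dataset$X, res$dataset$X[perm, ])
  # strict monotonicity on a non-constant column
  x <- ds$X[, 1]
  z <- res$dataset$X[, 1]
  expect_true(all(diff(z[order(x)])[diff(x[order(x)]) > 0] > 0))
})

test_that("covariate residualization orthogonalizes against the design", {
  set.seed(31)
  n <- 60
  ds <- make_toy_dataset(n_per_class = n / 2, seed = 3)
  cov <- data.frame(sample_id = ds$sample_ids,
                    age = rnorm(n, 70, 5), icv = rnorm(n, 1500, 100))
  out <- residualize_covariates(ds, cov)
  Cc <- scale(as.matrix(cov[, -1]), scale = FALSE)
  for (j in c(1, 5, 10))
    expect_true(all(abs(crossprod(Cc, out$X[, j])) < 1e-8))
  # a feature used as covariate residualizes to zero
  cov2 <- data.frame(sample_id = ds$sample_ids, f = ds$X[, 2])
  out2 <- residualize_covariates(ds, cov2)
  expect_true(all(abs(out2$X[, 2]) < 1e-10))
  # intercept-only: mean centering
  out3 <- residualize_covariates(ds, matrix(numeric(0), nrow = n, ncol = 0))
  expect_equal(out3$X, scale(ds$X, scale = FALSE), ignore_attr = TRUE)
  # collinear covariates are rejected by name
  cov4 <- data.frame(sample_id = ds$sample_ids, a = 1:n, b = 2 * (1:n))
  expect_error(residualize_covariates(ds, cov4), "collinear.*b")
})

test_that("uncorrelated covariates leave features nearly unchanged at large n", {
  set.seed(77)
  gen <- generate_cohort(cohort_spec(n_per_class = 1000, d_imaging = 3,
                                     d_snp = 2, seed = 15))
  ds <- gen$dataset
  cov <- data.frame(sample_id = ds$sample_ids, z = rnorm(2000))
  out <- residualize_covariates(ds, cov)
  expect_gt(cor(out$X[, 1], ds$X[, 1]), 0.99)
})

test_that("re-fitting already-normalized data is idempotent up to eps", {
  ds <- make_toy_dataset(n_per_class = 15, seed = 6)
  once <- normalize_dataset(ds)
  twice <- normalize_dataset(once$dataset)
  expect_equal(twice$dataset$X, once$dataset$X, tolerance = 1e-6)
})
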