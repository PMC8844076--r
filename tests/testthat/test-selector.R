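make_problem <- function(d = 10, n = 40, cc = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(d * n), d, n)
  y <- factor(rep(letters[1:cc], length.out = n))
  list(X = X, Y = label_matrix(y), bm = list(m1 = seq_len(d %/% 2),
                                             m2 = (d %/% 2 + 1):d))
}

test_that("gamma = 0 reproduces the intercept-augmented least squares", {
  p <- make_problem(d = 10, n = 40)
  fit <- fit_weight_matrix(p$X, p$Y, p$bm, gamma1 = 0, gamma2 = 0,
                           tol = 1e-12)
  oracle <- ls_oracle(p$X, p$Y)
  expect_equal(unname(fit$W), unname(oracle$W), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(oracle$intercept), tolerance = 1e-6)
  expect_monotone_trace(fit)
})

test_that("huge gamma2 shrinks the weight matrix to numerical zero", {
  p <- make_problem(d = 8, n = 30, seed = 3)
  fit <- fit_weight_matrix(p$X, p$Y, p$bm, gamma1 = 0, gamma2 = 1e6)
  expect_lt(sqrt(sum(fit$W^2)), 1e-4)
  expect_monotone_trace(fit)
})

test_that("the IRLS fixed point is a local minimum of the smoothed objective", {
  set.seed(17)
  d <- 4; n <- 12; cc <- 2
  X <- matrix(rnorm(d * n), d, n)
  y <- factor(rep(c("a", "b"), n / 2))
  Y <- label_matrix(y)
  bm <- list(m1 = 1:2, m2 = 3:4)
  g1 <- 0.3; g2 <- 0.4; eps <- 1e-8
  fit <- fit_weight_matrix(X, Y, bm, gamma1 = g1, gamma2 = g2,
                           eps_smooth = eps, max_iter = 1000, tol = 1e-12,
                           intercept = FALSE)
  obj_at <- function(W) mmselect:::mm_objective_smooth(W, X, Y, bm, g1, g2,
                                                       eps,
                                                       loss_scale = 1 / n)
  base <- obj_at(fit$W)
  worse <- replicate(1000, {
    delta <- matrix(rnorm(d * cc), d, cc)
    delta <- delta / sqrt(sum(delta^2)) * 1e-3
    obj_at(fit$W + delta)
  })
  expect_true(all(worse >= base - 1e-12))
})

test_that("fits are deterministic and independent of sample ordering", {
  p <- make_problem(d = 12, n = 50, seed = 9)
  f1 <- fit_weight_matrix(p$X, p$Y, p$bm)
  f2 <- fit_weight_matrix(p$X, p$Y, p$bm)
  expect_identical(f1$W, f2$W)
  perm <- sample(ncol(p$X))
  f3 <- fit_weight_matrix(p$X[, perm], p$Y[, perm], p$bm)
  expect_equal(f1$W, f3$W, tolerance = 1e-9)
  expect_monotone_trace(f1)
})

test_that("row sparsity is monotone in gamma2", {
  p <- make_problem(d = 20, n = 60, seed = 23)
  counts <- sapply(c(0.01, 0.1, 1, 10), function(g2) {
    fit <- fit_weight_matrix(p$X, p$Y, p$bm, gamma1 = 0, gamma2 = g2,
                             max_iter = 500)
    sum(sqrt(rowSums(fit$W^2)) > 1e-6)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("the G1 penalty keeps both modalities in play when both carry signal", {
  gen <- generate_cohort(cohort_spec(n_per_class = 40, d_imaging = 15,
                                     d_snp = 40, effect_size = 1.2,
                                     snp_effect = 0.25, seed = 31))
  fit <- mmfs(gen$dataset, k_per_modality = 3, classifier = FALSE)
  imp <- fit$selection$importance
  for (b in names(fit$reduced_blocks))
    expect_gt(max(imp[fit$reduced_blocks[[b]]]), 1e-8)
  expect_length(fit$selection$weights$imaging, 3)
  expect_length(fit$selection$weights$snp, 3)
})

test_that("selection arithmetic follows the sum-of-absolute-weights rule", {
  W <- rbind(c(0.25, -0.25), c(0.05, 0.05), c(-0.2, 0.2),
             c(1, 1), c(0, 0.5))
  bm <- list(a = 1:3, b = 4:5)
  X <- matrix(rnorm(4 * 5), 4, 5)
  sel <- select_and_weight(W, X, bm, k_per_modality = 2)
  # importances: a block = (0.5, 0.1, 0.4) -> pick rows 1, 3; weights 5/9, 4/9
  expect_equal(sel$selected$a, c(1L, 3L))
  expect_equal(unname(sel$weights$a), c(5 / 9, 4 / 9))
  expect_equal(sum(sel$weights$b), 1)
  # classifier input: selected columns times mean-one rescaled weights
  cw <- unlist(sel$classifier_weights, use.names = FALSE)
  expect_equal(unname(sel$reweighted),
               unname(sweep(X[, c(1, 3, 4, 5)], 2, cw, `*`)))
  expect_equal(mean(sel$classifier_weights$a), 1)
  # k = block width keeps everything, weights still sum to one
  sel_all <- select_and_weight(W, X, bm, k_per_modality = 5)
  expect_equal(sel_all$selected$a, 1:3)
  expect_equal(sum(sel_all$weights$a), 1)
  # ties break by ascending index
  Wt <- rbind(c(1, 0), c(1, 0), c(1, 0), c(2, 0), c(1, 1))
  selt <- select_and_weight(Wt, X, list(a = 1:3, b = 4:5), 2)
  expect_equal(selt$selected$a, c(1L, 2L))
  # an all-zero modality block is an error
  Wz <- W; Wz[4:5, ] <- 0
  expect_error(select_and_weight(Wz, X, bm, 2), "no informative features")
  expect_error(select_and_weight(W, X[, 1:4], bm, 2), "columns")
})

test_that("non-finite inputs and invalid configs are rejected", {
  p <- make_problem()
  Xb <- p$X; Xb[1, 1] <- NA
  expect_error(fit_weight_matrix(Xb, p$Y, p$bm), "non-finite")
  expect_error(fit_weight_matrix(p$X, p$Y, p$bm, gamma1 = -1), ">= 0")
  expect_error(fit_weight_matrix(p$X, p$Y, p$bm, tol = 0), "tol")
  expect_error(fit_weight_matrix(p$X, p$Y, list(m = 1:3)), "partition")
  expect_error(fit_weight_matrix(p$X, p$Y[, 1:10], p$bm), "mismatch")
})
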