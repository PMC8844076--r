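# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately loop over classes/samples/rows exactly
# as the defining formulas are written, and share no code with R/.

# Fisher score: between-class divergence over class-size-weighted
# within-class divergence, one feature at a time.
fisher_oracle <- function(X, y, eps = 0) {
  y <- as.factor(y)
  classes <- levels(y)
  d <- ncol(X)
  scores <- numeric(d)
  for (i in seq_len(d)) {
    mu_i <- mean(X[, i])
    s_b <- 0
    s_w <- 0
    for (k in classes) {
      xk <- X[y == k, i]
      n_k <- length(xk)
      mu_ik <- mean(xk)
      s_b <- s_b + n_k * (mu_ik - mu_i)^2
      inner <- 0
      for (j in seq_len(n_k)) inner <- inner + (xk[j] - mu_ik)^2
      s_w <- s_w + n_k * inner
    }
    scores[i] <- s_b / (s_w + eps)
  }
  scores
}

l21_oracle <- function(W) {
  total <- 0
  for (i in seq_len(nrow(W))) {
    row_sq <- 0
    for (j in seq_len(ncol(W))) row_sq <- row_sq + W[i, j]^2
    total <- total + sqrt(row_sq)
  }
  total
}

g1_oracle <- function(W, block_map) {
  total <- 0
  for (j in seq_len(ncol(W)))
    for (b in block_map) {
      blk_sq <- 0
      for (i in b) blk_sq <- blk_sq + W[i, j]^2
      total <- total + sqrt(blk_sq)
    }
  total
}

# Intercept-augmented least-squares via the normal equations: regress each
# class indicator on [1; X] and return the feature part of the coefficients.
ls_oracle <- function(X, Y) {
  A <- rbind(1, X)                        # (d+1) x N
  B <- solve(A %*% t(A), A %*% t(Y))      # (d+1) x c
  list(W = B[-1, , drop = FALSE], intercept = B[1, ])
}

# Small deterministic two-block dataset for structural tests.
make_toy_dataset <- function(n_per_class = 10, d_imaging = 4, d_snp = 6,
                             effect = 1.5, seed = 42) {
  gen <- generate_cohort(cohort_spec(
    n_per_class = n_per_class, d_imaging = d_imaging, d_snp = d_snp,
    k_informative_imaging = min(2, d_imaging),
    k_informative_snp = min(2, d_snp),
    effect_size = effect, snp_effect = 0.2, seed = seed))
  gen$dataset
}

expect_monotone_trace <- function(fit, tol = 1e-9) {
  expect_true(all(diff(fit$trace) <= tol))
}
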