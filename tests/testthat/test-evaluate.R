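test_that("stratified folds balance classes and partition the cohort", {
  y <- factor(rep(c("HC", "AD"), each = 25))
  f <- make_folds(y, 5, seed = 4)
  expect_equal(sort(unique(f)), 1:5)
  for (k in 1:5)
    expect_equal(as.vector(table(y[f == k])), c(5L, 5L))
  # deterministic given seed, different for another seed
  expect_identical(f, make_folds(y, 5, seed = 4))
  expect_false(identical(f, make_folds(y, 5, seed = 5)))
  # leave-one-out boundary
  floo <- make_folds(y, 50, seed = 1)
  expect_equal(sort(unique(floo)), 1:50)
  expect_equal(as.vector(table(floo)), rep(1L, 50))
  # a class smaller than the fold count is an error
  expect_error(make_folds(factor(c("a", "a", "a", "b")), 3, 1),
               "fewer folds")
})

test_that("confusion-matrix metrics follow their definitions in percent", {
  # TP=24, TN=25, FP=0, FN=1 with "AD" positive
  truth <- factor(c(rep("AD", 25), rep("HC", 25)))
  pred <- truth
  pred[1] <- "HC"
  m <- classification_metrics(truth, pred, positive = "AD")
  expect_equal(unname(m), c(98, 96, 100))
  # majority-class predictor on balanced labels scores exactly 50
  maj <- factor(rep("HC", 50), levels = c("AD", "HC"))
  expect_equal(unname(classification_metrics(truth, maj, "AD")["accuracy"]),
               50)
  # invariant to sample order
  perm <- sample(50)
  expect_equal(classification_metrics(truth[perm], pred[perm], "AD"), m)
})

test_that("a strongly separated cohort is classified perfectly in CV", {
  # a deterministic genotype contrast (class MAFs 0.3 vs 1.0) is required for
  # true separability: discrete allele counts overlap classes with
  # probability (1-p)^2 at any weaker contrast
  gen <- generate_cohort(cohort_spec(n_per_class = 50, d_imaging = 20,
                                     d_snp = 40, k_informative_imaging = 10,
                                     k_informative_snp = 10, effect_size = 3,
                                     snp_effect = 0.7, seed = 19))
  cv <- cross_validate(gen$dataset, n_folds = 5, seed = 2,
                       k_per_modality = 10)
  expect_equal(unname(cv$mean["accuracy"]), 100)
  expect_equal(cv$folds$accuracy, rep(100, 5))
  # report invariants
  expect_equal(unname(cv$mean),
               unname(colMeans(cv$folds[, c("accuracy", "sensitivity",
                                            "specificity")])),
               tolerance = 1e-12)
  expect_true(all(cv$selection_frequency <= 5))
  expect_equal(sort(unique(cv$assignment)), 1:5)
})

test_that("cross-validation is reproducible and test sets are sized right", {
  gen <- generate_cohort(cohort_spec(n_per_class = 15, d_imaging = 8,
                                     d_snp = 20, effect_size = 1.5,
                                     seed = 23))
  cv1 <- cross_validate(gen$dataset, n_folds = 5, seed = 7)
  cv2 <- cross_validate(gen$dataset, n_folds = 5, seed = 7)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$selected, cv2$selected)
  expect_equal(as.vector(table(cv1$assignment)), rep(6L, 5))
})

test_that("stable planted features are selected across folds", {
  runs <- sapply(1:5, function(s) {
    gen <- generate_cohort(cohort_spec(n_per_class = 50, d_imaging = 20,
                                       d_snp = 60, effect_size = 2,
                                       snp_effect = 0.3, seed = s))
    cv <- cross_validate(gen$dataset, n_folds = 5, seed = s + 50)
    everytime <- names(cv$selection_frequency)[cv$selection_frequency == 5]
    truth_names <- c(sprintf("img_%03d", gen$truth$imaging),
                     sprintf("snp_%04d", gen$truth$snp))
    length(intersect(everytime, truth_names)) > 0
  })
  expect_gte(mean(runs), 0.8)
})

test_that("training state never depends on test-fold labels", {
  gen <- generate_cohort(cohort_spec(n_per_class = 20, d_imaging = 10,
                                     d_snp = 25, effect_size = 1.5,
                                     seed = 41))
  ds <- gen$dataset
  train <- mm_subset_samples(ds, c(1:15, 21:35))
  test1 <- mm_subset_samples(ds, c(16:20, 36:40))
  test2 <- test1
  test2$y <- factor(rev(as.character(test1$y)), levels = levels(test1$y))
  r1 <- train_eval_fold(train, test1)
  r2 <- train_eval_fold(train, test2)
  fingerprint <- function(m)
    list(norm = m$norm, fisher = lapply(m$fisher, function(f)
      list(f$scores, f$retained)),
      W = m$fit$W, sel = m$selection$weights,
      svm = list(m$svm$SV, m$svm$coefs, m$svm$rho))
  expect_identical(fingerprint(r1$model), fingerprint(r2$model))
  expect_identical(r1$selected, r2$selected)
  # a test class absent from training is an error
  train_c1 <- mm_subset_samples(ds, which(ds$y == "C1")[1:10],
                                drop_levels = TRUE)
  expect_error(train_eval_fold(train_c1, test1), "absent from training")
})

test_that("permuted-label cohorts score at chance", {
  accs <- sapply(1:8, function(s) {
    gen <- generate_cohort(cohort_spec(n_per_class = 40, d_imaging = 10,
                                       d_snp = 30, effect_size = 1.5,
                                       snp_effect = 0.2, seed = s))
    ds <- gen$dataset
    set.seed(1000 + s)
    ds$y <- sample(ds$y)
    cross_validate(ds, n_folds = 5, seed = s)$mean["accuracy"]
  })
  # three binomial standard errors around chance for the pooled predictions
  expect_lt(abs(mean(accs) - 50), 3 * sqrt(0.25 / (80 * length(accs))) * 100)
})
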