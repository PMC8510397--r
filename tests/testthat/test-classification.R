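test_that("folds are stratified, disjoint, exhaustive and reproducible", {
  y <- rep(c("a", "b"), each = 50)
  fm <- make_folds(y, k = 10, repeats = 3, seed = 5)
  expect_length(fm$folds, 3)
  for (fold in fm$folds) {
    expect_setequal(unique(fold), 1:10)
    for (f in 1:10) {
      expect_identical(sum(fold == f & y == "a"), 5L)
      expect_identical(sum(fold == f & y == "b"), 5L)
    }
  }
  expect_identical(make_folds(y, 10, 3, seed = 5), fm)
  expect_false(identical(make_folds(y, 10, 3, seed = 6)$folds, fm$folds))
  expect_warning(fm2 <- make_folds(rep(c("a", "b"), c(4, 40)), k = 10),
                 "reducing k")
  expect_identical(fm2$k, 4L)
  expect_error(make_folds(rep("a", 20)), "2 classes")
})

test_that("classifiers fit their training contracts", {
  set.seed(40)
  X <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 8), 50, 2))
  y <- rep(c("lo", "hi"), each = 50)
  clf <- train_classifier(X, y, "lda")
  expect_identical(mean(predict(clf, X) != y), 0)
  knn1 <- train_classifier(X, y, "knn", params = list(k = 1))
  expect_identical(mean(predict(knn1, X) != y), 0)
})

test_that("lda accepts rank-deficient clr coordinates via the pivot basis", {
  set.seed(41)
  mus <- list(a = c(1.5, 0, 0), b = c(-1.5, 0, 0))
  spec <- generator_spec(4, mus, 0.4, c(40, 40))
  X <- generate_composition(spec, seed = 42)
  Rclr <- clr_transform(X)
  expect_no_error(clf <- train_classifier(Rclr, X$labels, "lda"))
  pred_clr <- predict(clf, Rclr)
  # decision-equivalent to training on pivot coordinates directly
  Rilr <- pivot_ilr(X)
  pred_ilr <- predict(train_classifier(Rilr, X$labels, "lda"), Rilr)
  expect_identical(as.character(pred_clr), as.character(pred_ilr))
})

test_that("the network separates linearly separable classes", {
  spec <- size_effect_spec()
  X <- generate_composition(spec, seed = 11)
  R <- pivot_ilr(X)
  set.seed(43)
  hold <- sample(600, 120)
  m <- mlp_classifier(R$values[-hold, ], X$labels[-hold], seed = 44)
  expect_lt(mean(predict(m, R$values[hold, ]) != X$labels[hold]), 0.05)
  expect_lt(m$best_epoch, 101)
  P <- predict(m, R$values[hold, ], type = "prob")
  expect_equal(rowSums(P), rep(1, 120), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("cross-validation is deterministic and leak-free", {
  spec <- size_effect_spec(n_per_class = 40L, D = 6L)
  X <- generate_composition(spec, seed = 50)
  r1 <- cv_misclassification(X, replacement = "none", representation = "clr",
                             classifier = "lda", k = 5, repeats = 2,
                             seed = 9, audit = TRUE)
  r2 <- cv_misclassification(X, replacement = "none", representation = "clr",
                             classifier = "lda", k = 5, repeats = 2, seed = 9)
  expect_identical(r1$records, r2$records)
  expect_equal(r1$mean_rate, mean(tapply(r1$records$rate, r1$records$rep,
                                         mean)))
  for (a in attr(r1, "fit_rows"))
    expect_length(intersect(a$fit_rows, a$test_rows), 0)
  expect_true(all(r1$records$rate >= 0 & r1$records$rate <= 1))
})

test_that("shuffled labels give chance-level misclassification", {
  spec <- size_effect_spec(n_per_class = 100L, D = 6L)
  X <- generate_composition(spec, seed = 51)
  ynull <- with_fixed_seed(52, sample(rep(c("a", "b"), each = 100)))
  r <- cv_misclassification(X, y = ynull, replacement = "none",
                            representation = "clr", classifier = "lda",
                            k = 10, repeats = 5, seed = 53)
  expect_equal(r$mean_rate, 0.5, tolerance = 0.05)
})

test_that("log-ratio representations beat raw coordinates under a size effect", {
  spec <- size_effect_spec()
  X <- generate_composition(spec, seed = 54)
  g <- benchmark_grid(X, replacements = "none",
                      representations = c("raw", "clr", "ilr"),
                      classifiers = c("lda", "knn"), k = 10, repeats = 2,
                      seed = 55)
  s <- g$summary
  expect_identical(nrow(s), 6L)
  expect_identical(nrow(g$records), 6L * 20L)
  for (clf in c("lda", "knn")) {
    raw <- s$mean_rate[s$representation == "raw" & s$classifier == clf]
    expect_lt(s$mean_rate[s$representation == "clr" & s$classifier == clf],
              raw)
    expect_lt(s$mean_rate[s$representation == "ilr" & s$classifier == clf],
              raw)
  }
  expect_null(g$failures)
})

test_that("replacement inside cross-validation uses training information only", {
  cen <- censored_scenario(seed = 60, n_per_class = 60L, D = 6L)
  r <- cv_misclassification(cen$data, replacement = "bdls_pls",
                            representation = "ilr_var", classifier = "lda",
                            k = 5, repeats = 1, seed = 61)
  expect_true(is.finite(r$mean_rate))
  expect_lt(r$mean_rate, 0.5)
  # a grid cell that fails is reported, the rest of the grid continues
  g <- benchmark_grid(cen$data, replacements = "none",
                      representations = c("raw", "clr"), classifiers = "lda",
                      k = 5, repeats = 1, seed = 62)
  expect_identical(nrow(g$failures), 2L)   # masked cells, no replacement
})
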