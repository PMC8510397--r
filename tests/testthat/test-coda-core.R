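test_that("closure rescales rows to kappa without changing ratios", {
  expect_equal(close_composition(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  expect_equal(close_composition(c(1, 1), kappa = 100), c(50, 50))
  set.seed(1)
  X <- random_positive(20, 5)
  C1 <- close_composition(X, 1)
  expect_equal(rowSums(C1), rep(1, 20), tolerance = 1e-10)
  expect_equal(close_composition(C1, 1), C1)              # idempotent
  expect_equal(C1[, 2] / C1[, 5], X[, 2] / X[, 5])        # ratios kept
  expect_error(close_composition(c(1, -2, 3)), "cell")
  expect_error(close_composition(c(1, 2), kappa = 0), "kappa")
})

test_that("z-scores have mean 0 and sample variance 1 per column", {
  Z <- zscore_columns(cbind(a = c(1, 2, 3), b = c(10, 30, 20)))
  expect_equal(Z[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(colMeans(Z), c(a = 0, b = 0), tolerance = 1e-10)
  expect_equal(apply(Z, 2, sd), c(a = 1, b = 1), tolerance = 1e-10)
  # reconstruction from the recorded centre/scale round-trips the input
  back <- sweep(sweep(Z, 2, attr(Z, "scale"), "*"), 2, attr(Z, "center"), "+")
  expect_equal(back, cbind(c(1, 2, 3), c(10, 30, 20)), ignore_attr = TRUE)
  expect_error(zscore_columns(cbind(ok = 1:3, flat = c(5, 5, 5))), "flat")
})

test_that("geometric mean is computed in log space", {
  expect_equal(geometric_mean(c(1, 1, 1)), 1)
  expect_equal(geometric_mean(c(4, 2, 1)), 2)
  # would overflow/underflow if evaluated as a product
  expect_equal(geometric_mean(c(1e-300, 1e+300)), 1)
  expect_error(geometric_mean(c(1, 0, 2)), "positive")
})

test_that("clr maps to zero-sum coefficients and inverts to the closed composition", {
  expect_equal(drop(clr_transform(c(1, 1, 1, 1))$values), rep(0, 4))
  expect_equal(drop(clr_transform(c(exp(2), exp(-1), exp(-1)))$values),
               c(2, -1, -1))
  set.seed(2)
  X <- random_positive(30, 6)
  Y <- clr_transform(X)
  expect_lt(max(abs(rowSums(Y$values))), 1e-10)
  expect_equal(clr_inverse(Y, 1), close_composition(X, 1), tolerance = 1e-9)
  for (lambda in c(0.001, 1, 1000))                    # scale invariance
    expect_equal(clr_transform(lambda * X)$values, Y$values,
                 tolerance = 1e-10)
  expect_error(clr_transform(rbind(c(1, 0, 2))), "positive")
  xm <- composition_matrix(rbind(c(0, 1, 2), c(1, 2, 3)))
  expect_error(clr_transform(xm), "replacement")
})

test_that("pivot coordinates match the scalar formula and invert exactly", {
  expect_equal(drop(pivot_ilr(c(exp(1), 1))$values), sqrt(1 / 2),
               ignore_attr = TRUE)
  expect_equal(drop(pivot_ilr(c(1, 1, 1))$values), c(0, 0),
               ignore_attr = TRUE)
  expect_equal(drop(pivot_ilr(c(4, 2, 1))$values),
               c(sqrt(2 / 3) * log(4 / sqrt(2)), sqrt(1 / 2) * log(2)),
               ignore_attr = TRUE)
  set.seed(3)
  for (D in 2:10) {                      # oracle equivalence, 100 rows
    X <- random_positive(10, D)
    Z <- pivot_ilr(X)$values
    for (i in 1:10)
      expect_equal(Z[i, ], naive_pivot(X[i, ]), tolerance = 1e-10,
                   ignore_attr = TRUE)
    expect_equal(pivot_ilr_inverse(pivot_ilr(X)), close_composition(X, 1),
                 tolerance = 1e-9)
  }
  expect_error(pivot_ilr(c(1, 2, 3), order = c(1, 1, 2)), "permutation")
})

test_that("pivot coordinates are an isometry of the clr geometry", {
  set.seed(4)
  X <- random_positive(25, 7)
  dclr <- dist(clr_transform(X)$values)
  for (ord in list(1:7, 7:1, sample(7))) {
    Z <- pivot_ilr(X, order = ord)
    expect_equal(as.numeric(dist(Z$values)), as.numeric(dclr),
                 tolerance = 1e-9)
    # norms of matching rows agree too
    expect_equal(sqrt(rowSums(Z$values^2)),
                 sqrt(rowSums(clr_transform(X)$values^2)), tolerance = 1e-9)
    # round trip restores the original part order
    expect_equal(pivot_ilr_inverse(Z), close_composition(X, 1),
                 tolerance = 1e-9)
  }
  # permutation invariance: distances unaffected by reordering parts
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  expect_equal(as.numeric(dist(clr_transform(X[, perm])$values)),
               as.numeric(dclr), tolerance = 1e-10)
})

test_that("ilr_var ordering ranks parts by class association of their logs", {
  set.seed(5)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  X <- random_positive(n, 4, sdlog = 0.1)
  X[y == "b", 3] <- X[y == "b", 3] * 20   # only part 3 differs by class
  ord <- ilr_var_order(X, y)
  expect_equal(ord[1], 3)
  # determinism under a fixed generation seed
  set.seed(6)
  Xn <- random_positive(40, 5)
  yn <- rep(c("a", "b"), each = 20)
  expect_identical(as.integer(ilr_var_order(Xn, yn)),
                   as.integer(ilr_var_order(Xn, yn)))
  # exact ties broken by the original column index
  Xt <- cbind(Xn[, 1], Xn[, 1], Xn[, 2])
  ot <- ilr_var_order(Xt, yn)
  expect_lt(which(ot == 1), which(ot == 2))
  expect_error(ilr_var_order(Xn, rep("a", 40)), "2 classes")
})

test_that("preprocess dispatches every representation with its contract", {
  M <- rbind(c(1, exp(1)), c(exp(1), 1))
  expect_equal(unname(preprocess(M, "log")$values),
               rbind(c(0, 1), c(1, 0)))
  set.seed(7)
  X <- random_positive(30, 5)
  cs <- preprocess(X, "closed_scale")
  expect_equal(colMeans(cs$values), rep(0, 5), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(apply(cs$values, 2, sd), rep(1, 5), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(preprocess(X, "clr")$values, clr_transform(X)$values)
  expect_identical(preprocess(X, "standardized")$representation, "scale")
  y <- rep(c("u", "v"), 15)
  iv <- preprocess(X, "ilr_var", y = y)
  expect_identical(iv$representation, "ilr_var")
  expect_identical(as.integer(iv$part_order), as.integer(ilr_var_order(X, y)))
  expect_error(preprocess(X, "ilr_var"), "labels")
})

test_that("closure induces the negativity bias in covariances and correlations", {
  set.seed(8)
  X <- random_positive(100, 4)
  d <- closure_bias_diagnostic(X)
  expect_lt(max(abs(d$cov_rowsums)), 1e-10)   # algebraic identity
  # two closed parts are perfectly negatively correlated
  d2 <- closure_bias_diagnostic(random_positive(50, 2))
  expect_equal(unname(d2$cor[1, 2]), -1, tolerance = 1e-12)
  # independent lognormal parts: closure still forces at least one
  # negative correlation for every part
  set.seed(9)
  d5 <- closure_bias_diagnostic(random_positive(500, 5))
  expect_true(all(d5$min_offdiag_cor < 0))
  expect_identical(d5$n_parts_any_negative, 5L)
})
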