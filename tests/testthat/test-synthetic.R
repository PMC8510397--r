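test_that("the generator realises the requested logistic-normal structure", {
  # degenerate covariance is rejected
  expect_error(generator_spec(4, list(a = rep(0, 3)), matrix(0, 3, 3), 10),
               "positive-definite")
  # near-zero spread: rows of one class are proportional to one composition
  spec0 <- generator_spec(5, list(a = c(1, 0, -1, 0.5)), 1e-6, 20)
  X0 <- generate_composition(spec0, seed = 1)
  cl <- close_composition(X0$values, 1)
  expect_lt(max(abs(sweep(cl, 2, cl[1, ], "/") - 1)), 1e-3)
  expect_true(all(X0$values > 0))
  # CLT: empirical latent mean within 3 standard errors of the spec mean
  mu <- c(0.5, -1, 0.25, 0)
  spec <- generator_spec(5, list(a = mu), 0.5, 10000)
  X <- generate_composition(spec, seed = 2)
  Z <- pivot_ilr(X)$values
  se <- 0.5 / sqrt(10000)
  expect_true(all(abs(colMeans(Z) - mu) < 3 * se))
  # the latent coordinates are recovered exactly by the forward map
  expect_equal(Z, unname(attr(X, "ilr")), tolerance = 1e-9,
               ignore_attr = TRUE)
  # totals follow the requested lognormal
  lt <- log(rowSums(X$values))
  expect_lt(abs(mean(lt) - log(1000)), 3 * 0.5 / sqrt(10000))
  # reproducibility
  expect_identical(generate_composition(spec0, seed = 1)$values, X0$values)
})

test_that("adulteration interpolates towards the contaminant in the simplex", {
  set.seed(3)
  spec <- generator_spec(6, list(pure = rep(0, 5)), 0.4, 30)
  X <- generate_composition(spec, seed = 4)
  contaminant <- c(10, 1, 1, 1, 1, 1)
  lo <- apply_adulteration(X, contaminant, alpha = 1e-9)
  expect_equal(close_composition(lo$values, 1),
               close_composition(X$values, 1), tolerance = 1e-6)
  hi <- apply_adulteration(X, contaminant, alpha = 1 - 1e-12)
  expect_equal(unname(hi$values[1, ] / sum(hi$values[1, ])),
               unname(close_composition(contaminant, 1)), tolerance = 1e-6)
  expect_error(apply_adulteration(X, contaminant, alpha = 1), "alpha")
  # totals (the size effect) are preserved
  mid <- apply_adulteration(X, contaminant, alpha = 0.4)
  expect_equal(rowSums(mid$values), rowSums(X$values), tolerance = 1e-9)
  expect_true(all(grepl("_adulterated$", as.character(mid$labels))))
  # partial adulteration relabels only the selected rows
  part <- apply_adulteration(X, contaminant, alpha = 0.4, fraction = 0.5,
                             seed = 5)
  expect_identical(sum(grepl("_adulterated$", as.character(part$labels))),
                   15L)
})

test_that("adulterated samples separate from pure ones in compositional PCA", {
  spec <- generator_spec(8, list(pure = rep(0, 7)), 0.4, 200)
  X <- generate_composition(spec, seed = 6)
  contaminant <- c(8, 4, rep(0.5, 6))
  A <- apply_adulteration(X, contaminant, alpha = 0.5, fraction = 0.5,
                          seed = 7)
  p <- pca_coordinates(clr_transform(A))
  grp <- grepl("_adulterated$", as.character(A$labels))
  gap <- abs(mean(p$scores[grp, 1]) - mean(p$scores[!grp, 1]))
  expect_gt(gap, sd(p$scores[, 1]))
})

test_that("left-censoring hits the target rate and keeps the truth", {
  spec <- generator_spec(8, list(a = rep(0, 7)), ar1_cov(7), 500)
  X <- generate_composition(spec, seed = 8)
  cen <- censor_below_dl(X, 0.0775)
  expect_equal(mean(cen$mask), 0.0775, tolerance = 0.01)
  # masked strictly below, unmasked at or above their limit
  dlm <- matrix(cen$detection_limits, nrow(cen$mask), ncol(cen$mask),
                byrow = TRUE)
  expect_true(all(cen$truth[cen$mask] < dlm[cen$mask]))
  expect_true(all(cen$truth[!cen$mask] >= dlm[!cen$mask]))
  expect_true(all(is.na(cen$data$values[cen$mask])))
  # zero rate: empty mask, data untouched
  cen0 <- censor_below_dl(X, 0)
  expect_false(any(cen0$mask))
  expect_error(censor_below_dl(X, 1), "target_rate")
})

test_that("the honey-like conditions produce the documented layout", {
  sim <- simulate_honey_like(seed = 3)
  expect_identical(nrow(sim$data$values), 429L)   # 201 + 45 + 183
  expect_identical(ncol(sim$data$values), 12L)
  expect_identical(as.vector(table(sim$label3)[c("honey", "syrup",
                                                 "adulterated")]),
                   c(201L, 45L, 183L))
  expect_lt(abs(mean(sim$mask) - 0.0775), 0.01)
  expect_identical(nlevels(sim$data$labels), 13L)  # 6 pure + Sy + 6 adult.
})

test_that("class separation survives censoring plus censored-PLS imputation", {
  f_stat <- function(values, y) {
    p <- pca_coordinates(clr_transform(values))
    summary(aov(p$scores[, 1] ~ y))[[1]]$`F value`[1]
  }
  ratios <- sapply(1:3, function(s) {
    mu <- with_fixed_seed(s, lapply(1:2, function(i) rnorm(7, 0, 1)))
    spec <- generator_spec(8, mu, ar1_cov(7), c(100, 100))
    X <- generate_composition(spec, seed = 100 + s)
    cen <- censor_below_dl(X, 0.0775)
    imp <- suppressWarnings(replace_bdls_pls(cen$data))
    f_stat(imp$data$values, X$labels) / f_stat(cen$truth, X$labels)
  })
  expect_true(all(abs(ratios - 1) < 0.2))
})
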