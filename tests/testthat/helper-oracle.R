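# Independent scalar evaluation of the pivot-coordinate formula
# z_j = sqrt((D-j)/(D-j+1)) * log(x_j / gm(x_{j+1..D})), written as plain
# loops so it shares no code with the matrix implementation it checks.
naive_pivot <- function(x) {
  D <- length(x)
  z <- numeric(D - 1)
  for (j in seq_len(D - 1)) {
    rest <- x[(j + 1):D]
    gm <- prod(rest)^(1 / length(rest))
    z[j] <- sqrt((D - j) / (D - j + 1)) * log(x[j] / gm)
  }
  z
}

# Random strictly positive compositions for property tests.
random_positive <- function(n, D, meanlog = 0, sdlog = 1) {
  matrix(rlnorm(n * D, meanlog, sdlog), n, D)
}

# AR(1) covariance used as the correlated logistic-normal condition in the
# imputation-recovery studies.
ar1_cov <- function(m, rho = 0.7, sd = 0.7) {
  sd^2 * rho^abs(outer(seq_len(m), seq_len(m), "-"))
}

# clr-space root-mean-square error of imputed cells against the
# pre-censoring truth.
clr_rmse <- function(completed, truth, mask) {
  a <- clr_transform(completed)$values
  b <- clr_transform(truth)$values
  sqrt(mean((a[mask] - b[mask])^2))
}

# Two-class correlated dataset with left-censoring, shared by the
# imputation tests and the acceptance suite.
censored_scenario <- function(seed, n_per_class = 100L, D = 8L,
                              rate = 0.10) {
  mu <- with_fixed_seed(seed, lapply(1:2, function(i) rnorm(D - 1, 0, 1)))
  spec <- generator_spec(D, mu, ar1_cov(D - 1), rep(n_per_class, 2))
  X <- generate_composition(spec, seed = seed + 1000L)
  censor_below_dl(X, rate)
}

with_fixed_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# Write a small synthetic deposit-schema CSV (honey or saffron layout) for
# exercising the file loaders without network access.
write_synthetic_honey_csv <- function(path, seed = 42L) {
  elements <- c("Al", "B", "Ba", "Ca", "Fe", "K", "Mg", "Mn", "Na", "P",
                "Sr", "Zn")
  with_fixed_seed(seed, {
    labels <- c(rep(c("AC", "CA", "JU"), each = 4), rep("Sy", 3),
                rep(c("AAC", "ACA"), each = 3), rep("blind", 2))
    n <- length(labels)
    v <- matrix(round(rlnorm(n * 12, log(50), 1), 4), n, 12)
    df <- data.frame(sample = paste0(labels, seq_len(n)), class = labels)
    for (j in seq_along(elements)) df[[elements[j]]] <- v[, j]
    df[2, elements[1]] <- "ND"    # a non-detect sentinel
    df[3, elements[2]] <- "0"     # a rounded zero
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    df
  })
}

write_synthetic_saffron_csv <- function(path, seed = 43L) {
  elements <- c("Li", "B", "Na", "Mg", "Al", "K", "Ca", "V", "Mn", "Fe",
                "Co", "Ni", "Cu", "Zn", "Ga", "As", "Rb", "Sr", "Y",
                "Mo", "Cd", "Cs", "Ba", "Ce", "Pr", "Nd", "Sm", "Gd",
                "Pb")
  with_fixed_seed(seed, {
    labels <- c(rep("Iran", 8), rep("Spain", 4))
    n <- length(labels)
    v <- matrix(round(rlnorm(n * 29, log(5), 1), 4), n, 29)
    df <- data.frame(sample = paste0("sa", seq_len(n)), class = labels)
    for (j in seq_along(elements)) df[[elements[j]]] <- v[, j]
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    df
  })
}
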