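# Minimal univariate partial least squares (PLS1) by NIPALS.
# Deterministic; returns regression coefficients on the original predictor
# scale. Used inside the censored below-detection-limit EM imputation,
# where the response is the leading pivot coordinate of the part being
# imputed and the predictors are the remaining pivot coordinates.

pls1_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1L)
  xbar <- colMeans(X); ybar <- mean(y)
  E <- sweep(X, 2, xbar)
  f <- y - ybar
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    tt <- drop(E %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) { ncomp <- a - 1L; break }
    pvec <- drop(crossprod(E, tt)) / tt2
    qa <- sum(f * tt) / tt2
    E <- E - tcrossprod(tt, pvec)
    f <- f - tt * qa
    W[, a] <- w; P[, a] <- pvec; q[a] <- qa
  }
  if (ncomp == 0L) {
    coef <- numeric(p)
  } else {
    Wk <- W[, seq_len(ncomp), drop = FALSE]
    Pk <- P[, seq_len(ncomp), drop = FALSE]
    qk <- q[seq_len(ncomp)]
    coef <- drop(Wk %*% solve(crossprod(Pk, Wk), qk))
  }
  list(coef = coef, intercept = ybar - sum(xbar * coef), ncomp = ncomp)
}

pls1_predict <- function(fit, X) {
  drop(as.matrix(X) %*% fit$coef) + fit$intercept
}

# Choose the number of PLS components by k-fold cross-validation over
# 1..max_ncomp, minimizing RMSE. Deterministic fold assignment (round
# robin over the row order) so the EM imputation stays reproducible
# without consuming random numbers.
pls1_select_ncomp <- function(X, y, max_ncomp, folds = 5L) {
  n <- nrow(X)
  folds <- min(folds, n)
  fold_id <- rep_len(seq_len(folds), n)
  grid <- seq_len(max_ncomp)
  press <- numeric(length(grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (sum(tr) < 2L) next
    for (gi in seq_along(grid)) {
      fit <- pls1_fit(X[tr, , drop = FALSE], y[tr], grid[gi])
      pred <- pls1_predict(fit, X[!tr, , drop = FALSE])
      press[gi] <- press[gi] + sum((y[!tr] - pred)^2)
    }
  }
  grid[which.min(press)]
}
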