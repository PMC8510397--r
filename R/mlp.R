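#' Dense feed-forward neural network classifier
#'
#' A compact multilayer perceptron for class prediction from coordinate
#' representations: three ReLU hidden layers of 300, 128 and 64 units with
#' 10% dropout after the first two, a softmax output layer, mean squared
#' error on one-hot targets as the loss (mean absolute error tracked as the
#' metric), the Adam optimizer, an 80/20 train/validation split, and early
#' stopping when the validation loss has not improved for `patience`
#' epochs (best weights restored). A cross-entropy loss is available via
#' `loss = "cross_entropy"` but is not the default.
#'
#' The default training length (`epochs = 100`, `patience = 20`) is a fast
#' profile for resampling studies; `faithful = TRUE` switches to 500
#' epochs with patience 50.
#'
#' @param x numeric matrix of predictors (n x d).
#' @param y class labels (factor or coercible).
#' @param hidden integer vector of hidden-layer sizes.
#' @param dropout per-hidden-layer dropout rates.
#' @param epochs,patience training length and early-stopping patience.
#' @param batch_size minibatch size for Adam.
#' @param lr Adam learning rate.
#' @param val_fraction fraction of rows held out for validation.
#' @param loss `"mse"` (default) or `"cross_entropy"`.
#' @param faithful use the full 500-epoch / patience-50 profile.
#' @param seed integer seed for the split, the weight initialization, the
#'   shuffling and the dropout masks.
#' @param verbose print per-epoch losses.
#' @return an object of class `mlp_classifier` with a [predict][predict.mlp_classifier] method.
#' @export
mlp_classifier <- function(x, y, hidden = c(300L, 128L, 64L),
                           dropout = c(0.1, 0.1, 0), epochs = 100L,
                           patience = 20L, batch_size = 32L, lr = 1e-3,
                           val_fraction = 0.2, loss = c("mse", "cross_entropy"),
                           faithful = FALSE, seed = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  if (faithful) { epochs <- 500L; patience <- 50L }
  x <- as.matrix(x)
  y <- factor(y)
  lev <- levels(y)
  C <- length(lev)
  if (C < 2L) stop("need at least 2 classes")
  n <- nrow(x)
  Tmat <- diag(C)[as.integer(y), , drop = FALSE]     # one-hot targets
  dropout <- rep_len(dropout, length(hidden))
  with_seed(seed, {
    n_val <- max(1L, floor(val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- x[tr_idx, , drop = FALSE]; Ttr <- Tmat[tr_idx, , drop = FALSE]
    Xva <- x[val_idx, , drop = FALSE]; Tva <- Tmat[val_idx, , drop = FALSE]
    sizes <- c(ncol(x), hidden, C)
    L <- length(sizes) - 1L
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {                          # He initialization
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                    sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(v) v * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    best <- list(loss = Inf, W = W, b = b, epoch = 0L)
    wait <- 0L
    ntr <- nrow(Xtr)
    for (ep in seq_len(epochs)) {
      perm <- sample.int(ntr)
      for (start in seq(1L, ntr, by = batch_size)) {
        bi <- perm[start:min(start + batch_size - 1L, ntr)]
        Xb <- Xtr[bi, , drop = FALSE]; Tb <- Ttr[bi, , drop = FALSE]
        # forward with inverted dropout on the hidden activations
        A <- vector("list", L + 1L); A[[1L]] <- Xb
        Dm <- vector("list", L)
        for (l in seq_len(L - 1L)) {
          Z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
          H <- pmax(Z, 0)
          if (dropout[l] > 0) {
            keep <- matrix(stats::runif(length(H)) >= dropout[l],
                           nrow(H), ncol(H))
            H <- H * keep / (1 - dropout[l])
            Dm[[l]] <- keep
          }
          A[[l + 1L]] <- H
        }
        Zo <- sweep(A[[L]] %*% W[[L]], 2, b[[L]], "+")
        P <- softmax_rows(Zo)
        nb <- nrow(Xb)
        if (loss == "mse") {
          G <- 2 * (P - Tb) / (nb * C)
          dZ <- P * (G - rowSums(G * P))             # softmax jacobian
        } else {
          dZ <- (P - Tb) / nb
        }
        gW <- vector("list", L); gb <- vector("list", L)
        for (l in rev(seq_len(L))) {
          gW[[l]] <- crossprod(A[[l]], dZ)
          gb[[l]] <- colSums(dZ)
          if (l > 1L) {
            dA <- dZ %*% t(W[[l]])
            if (!is.null(Dm[[l - 1L]]))
              dA <- dA * Dm[[l - 1L]] / (1 - dropout[l - 1L])
            dZ <- dA * (A[[l]] > 0)
          }
        }
        step <- step + 1L
        corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
        for (l in seq_len(L)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
          W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) /
            (sqrt(vW[[l]] / corr2) + eps)
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
          b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) /
            (sqrt(vb[[l]] / corr2) + eps)
        }
      }
      Pva <- mlp_forward(Xva, W, b)
      val_loss <- if (loss == "mse") mean((Pva - Tva)^2)
                  else -mean(rowSums(Tva * log(pmax(Pva, 1e-12))))
      val_mae <- mean(abs(Pva - Tva))
      if (!is.finite(val_loss)) break
      if (verbose)
        message(sprintf("epoch %d: val loss %.5f, val MAE %.5f",
                        ep, val_loss, val_mae))
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, W = W, b = b, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  structure(list(W = best$W, b = best$b, levels = lev, loss = loss,
                 val_loss = best$loss, best_epoch = best$epoch,
                 hidden = hidden, seed = seed),
            class = "mlp_classifier")
}

mlp_forward <- function(X, W, b) {
  L <- length(W)
  A <- as.matrix(X)
  for (l in seq_len(L - 1L))
    A <- pmax(sweep(A %*% W[[l]], 2, b[[l]], "+"), 0)
  softmax_rows(sweep(A %*% W[[L]], 2, b[[L]], "+"))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Predict classes (or class probabilities) from a fitted network
#' @param object an `mlp_classifier`.
#' @param newdata numeric matrix of predictors.
#' @param type `"class"` for labels, `"prob"` for the softmax matrix.
#' @param ... ignored.
#' @return factor of predicted labels, or a probability matrix.
#' @export
predict.mlp_classifier <- function(object, newdata, type = c("class", "prob"),
                                   ...) {
  type <- match.arg(type)
  P <- mlp_forward(as.matrix(newdata), object$W, object$b)
  colnames(P) <- object$levels
  if (type == "prob") return(P)
  factor(object$levels[max.col(P, ties.method = "first")],
         levels = object$levels)
}
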