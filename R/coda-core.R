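#' Closure of compositions to a constant sum
#'
#' Rescales each composition (row) so its parts sum to `kappa`. Closure does
#' not change the ratios between parts: the result is compositionally
#' equivalent to the input, which is why every log-ratio method is invariant
#' to it.
#'
#' @param x positive numeric vector, matrix or [composition_matrix()].
#' @param kappa target row sum (> 0), e.g. 1 for proportions or 100 for
#'   percentages.
#' @return matrix (or vector, if `x` was a vector) of closed compositions.
#' @examples
#' close_composition(c(2, 3, 5))           # 0.2 0.3 0.5
#' close_composition(c(1, 1), kappa = 100) # 50 50
#' @export
close_composition <- function(x, kappa = 1) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    stop("'kappa' must be a single positive number")
  vec <- is.null(dim(x)) && !inherits(x, "composition_matrix")
  v <- comp_values(x, "closure")
  out <- kappa * v / rowSums(v)
  if (vec) drop(out) else out
}

#' Column-wise z-scores
#'
#' Standardizes each column to arithmetic mean 0 and sample variance 1
#' (denominator `n - 1`). This is the classical non-compositional
#' pre-processing used so that parts measured on very different scales (K
#' can exceed trace elements thousands-fold) get equal weight in a
#' multivariate method.
#'
#' @param X numeric matrix with `n >= 2` rows and no constant column.
#' @return matrix of the same shape; attributes `center` and `scale` hold
#'   the column means and standard deviations used.
#' @export
zscore_columns <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("z-scores need at least 2 rows")
  ctr <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  zero <- which(s == 0 | !is.finite(s))
  if (length(zero)) {
    nm <- colnames(X)[zero[1]]
    if (is.null(nm)) nm <- as.character(zero[1])
    stop("constant column (zero standard deviation): ", nm)
  }
  Z <- sweep(sweep(X, 2, ctr), 2, s, "/")
  attr(Z, "center") <- ctr
  attr(Z, "scale") <- s
  Z
}

#' Row-wise geometric mean
#'
#' Geometric mean of each composition, evaluated in log space
#' (`exp(mean(log(x)))`) so that products of many or extreme parts neither
#' overflow nor underflow.
#'
#' @param x positive numeric vector, matrix or [composition_matrix()].
#' @return numeric vector of per-row geometric means.
#' @examples
#' geometric_mean(c(4, 2, 1))  # 2
#' @export
geometric_mean <- function(x) {
  vec <- is.null(dim(x)) && !inherits(x, "composition_matrix")
  v <- comp_values(x, "geometric mean")
  gm <- exp(rowMeans(log(v)))
  if (vec) unname(drop(gm)) else gm
}

#' Centred log-ratio (clr) representation
#'
#' Maps each composition to the log of its parts relative to the row
#' geometric mean. The resulting rows sum to zero, so the D clr coefficients
#' live on a (D-1)-dimensional hyperplane; distances and angles computed on
#' them realise the Aitchison geometry of the simplex.
#'
#' @param X positive numeric matrix/vector or complete [composition_matrix()].
#' @return a [coordinate_matrix()] with representation `"clr"`.
#' @examples
#' clr_transform(c(exp(2), exp(-1), exp(-1)))  # 2 -1 -1
#' @export
clr_transform <- function(X) {
  v <- comp_values(X, "clr")
  L <- log(v)
  Y <- L - rowMeans(L)
  coordinate_matrix(Y, "clr", column_names = colnames(v))
}

#' @rdname clr_transform
#' @param Y clr coordinates (matrix or `coordinate_matrix`).
#' @param kappa row sum of the reconstructed compositions.
#' @return `clr_inverse` returns the closed composition matrix.
#' @export
clr_inverse <- function(Y, kappa = 1) {
  close_composition(exp(coord_values(Y)), kappa)
}

# Orthonormal pivot basis: D x (D-1) matrix V with ilr = log(x) %*% V and
# clr = ilr %*% t(V). Column j contrasts part j against the geometric mean
# of parts j+1..D.
pivot_basis <- function(D) {
  V <- matrix(0, D, D - 1L)
  for (j in seq_len(D - 1L)) {
    r <- D - j
    V[j, j] <- sqrt(r / (r + 1))
    V[(j + 1L):D, j] <- -1 / sqrt(r * (r + 1))
  }
  V
}

#' Pivot (isometric log-ratio) coordinates
#'
#' Maps D-part compositions to D-1 orthonormal log-ratio coordinates.
#' Coordinate j carries the relative dominance of part j with respect to
#' the geometric mean of the remaining parts j+1..D:
#' `z_j = sqrt((D-j)/(D-j+1)) * log(x_j / gm(x_{j+1..D}))`.
#' The map is an isometry between the Aitchison geometry of the simplex and
#' ordinary Euclidean geometry in D-1 dimensions.
#'
#' @param X positive numeric matrix/vector or complete [composition_matrix()].
#' @param order permutation of `1..D` giving the pivot sequence; the default
#'   is the natural column order of the input.
#' @return a [coordinate_matrix()] with representation `"ilr"`, carrying the
#'   `part_order` used.
#' @examples
#' pivot_ilr(c(exp(1), 1))  # sqrt(1/2) = 0.7071
#' @export
pivot_ilr <- function(X, order = NULL) {
  v <- comp_values(X, "pivot coordinates")
  D <- ncol(v)
  order <- check_order(order, D)
  vp <- v[, order, drop = FALSE]
  Z <- log(vp) %*% pivot_basis(D)
  cn <- colnames(vp)
  zn <- if (!is.null(cn)) paste0("z_", cn[-D]) else paste0("z", seq_len(D - 1L))
  coordinate_matrix(Z, "ilr", part_order = order, column_names = zn)
}

#' @rdname pivot_ilr
#' @param Z pivot coordinates (matrix or `coordinate_matrix`).
#' @param kappa row sum of the reconstructed compositions.
#' @return `pivot_ilr_inverse` returns the closed composition matrix in the
#'   original (un-permuted) part order.
#' @export
pivot_ilr_inverse <- function(Z, order = NULL, kappa = 1) {
  if (inherits(Z, "coordinate_matrix") && is.null(order)) order <- Z$part_order
  Zv <- coord_values(Z)
  if (is.null(dim(Z)) && !inherits(Z, "coordinate_matrix"))
    Zv <- matrix(as.numeric(Z), nrow = 1)
  D <- ncol(Zv) + 1L
  order <- check_order(order, D)
  Y <- Zv %*% t(pivot_basis(D))      # clr coefficients of the permuted parts
  Xp <- close_composition(exp(Y), kappa)
  inv <- integer(D)
  inv[order] <- seq_len(D)
  Xp[, inv, drop = FALSE]
}

check_order <- function(order, D) {
  if (is.null(order)) return(seq_len(D))
  order <- as.integer(order)
  if (length(order) != D || anyNA(order) || !setequal(order, seq_len(D)))
    stop("'order' must be a permutation of 1..", D)
  order
}

#' Order parts by association of log-concentration with the class label
#'
#' Ranks parts by the correlation ratio eta between `log(part)` and the
#' class factor: the square root of the between-class over total sum of
#' squares (the R of a one-way ANOVA). With two classes eta equals the
#' absolute point-biserial correlation. Used by the `ilr_var` representation
#' to put the most class-informative parts into the leading pivot
#' coordinates. Ties are broken by the original column index, so the
#' ordering is deterministic.
#'
#' @param X positive numeric matrix or complete [composition_matrix()].
#' @param y class labels (>= 2 classes); defaults to the labels carried by
#'   `X` when it is a `composition_matrix`.
#' @return integer permutation of `1..D`, most associated part first;
#'   attribute `"eta"` carries the per-part association in original order.
#' @export
ilr_var_order <- function(X, y = NULL) {
  if (is.null(y) && inherits(X, "composition_matrix")) y <- X$labels
  if (is.null(y)) stop("'y' (class labels) is required for ilr_var ordering")
  v <- comp_values(X, "ilr_var ordering")
  y <- factor(y)
  if (nlevels(y) < 2L) stop("ilr_var ordering needs at least 2 classes")
  L <- log(v)
  eta <- apply(L, 2, function(col) {
    tot <- sum((col - mean(col))^2)
    if (tot == 0) return(0)
    between <- sum(tapply(col, y, function(g) length(g) * (mean(g) - mean(col))^2))
    sqrt(between / tot)
  })
  ord <- order(-eta, seq_along(eta))  # stable: ties keep original index order
  structure(ord, eta = eta)
}

#' Dispatch a pre-processing representation
#'
#' Applies one of the pre-processing regimes compared throughout the
#' package to a complete composition table:
#' \describe{
#'   \item{raw}{identity (concentrations as measured)}
#'   \item{scale}{column z-scores of the raw concentrations}
#'   \item{log}{natural log of each entry}
#'   \item{log_scale}{log then column z-scores}
#'   \item{closed_scale}{closure of each row to 1, then column z-scores}
#'   \item{clr}{centred log-ratio coordinates}
#'   \item{ilr}{pivot coordinates in the natural part order}
#'   \item{ilr_var}{pivot coordinates after ordering parts by association
#'     of log(part) with the class label `y`}
#' }
#' The long aliases `standardized`, `log_standardized` and
#' `closed_standardized` are accepted.
#'
#' @param X positive numeric matrix or complete [composition_matrix()].
#' @param repr representation tag (see above).
#' @param y class labels, required for `"ilr_var"`; defaults to labels
#'   carried by `X`.
#' @return a [coordinate_matrix()] tagged with the representation.
#' @export
preprocess <- function(X, repr, y = NULL) {
  repr <- normalize_repr(repr)
  fit <- preprocess_fit(X, repr, y)
  preprocess_apply(fit, X)
}

# Split fit/apply so cross-validation can learn data-dependent parameters
# (z-score centre/scale, ilr_var ordering) on training folds only.
preprocess_fit <- function(X, repr, y = NULL) {
  repr <- normalize_repr(repr)
  v <- comp_values(X, paste0("representation '", repr, "'"))
  fit <- list(repr = repr)
  if (repr == "scale") {
    z <- zscore_columns(v)
    fit$center <- attr(z, "center"); fit$scale <- attr(z, "scale")
  } else if (repr == "log_scale") {
    z <- zscore_columns(log(v))
    fit$center <- attr(z, "center"); fit$scale <- attr(z, "scale")
  } else if (repr == "closed_scale") {
    z <- zscore_columns(close_composition(v, 1))
    fit$center <- attr(z, "center"); fit$scale <- attr(z, "scale")
  } else if (repr == "ilr_var") {
    if (is.null(y) && inherits(X, "composition_matrix")) y <- X$labels
    if (is.null(y)) stop("representation 'ilr_var' requires class labels 'y'")
    fit$order <- ilr_var_order(v, y)
  }
  fit
}

preprocess_apply <- function(fit, X) {
  v <- comp_values(X, paste0("representation '", fit$repr, "'"))
  switch(fit$repr,
    raw = coordinate_matrix(v, "raw", column_names = colnames(v)),
    scale = coordinate_matrix(
      sweep(sweep(v, 2, fit$center), 2, fit$scale, "/"),
      "scale", column_names = colnames(v)),
    log = coordinate_matrix(log(v), "log", column_names = colnames(v)),
    log_scale = coordinate_matrix(
      sweep(sweep(log(v), 2, fit$center), 2, fit$scale, "/"),
      "log_scale", column_names = colnames(v)),
    closed_scale = coordinate_matrix(
      sweep(sweep(close_composition(v, 1), 2, fit$center), 2, fit$scale, "/"),
      "closed_scale", column_names = colnames(v)),
    clr = clr_transform(v),
    ilr = pivot_ilr(v),
    ilr_var = {
      cm <- pivot_ilr(v, order = as.integer(fit$order))
      cm$representation <- "ilr_var"
      cm
    })
}

#' Diagnose the negativity bias induced by closure
#'
#' Closing compositions to a constant row sum forces every part's sample
#' covariances with the remaining parts to sum to minus its own variance:
#' each row of the covariance matrix of closed data sums to zero exactly.
#' Correlations of closed data are therefore biased towards negative values
#' even when the underlying (unclosed) variables are independent — the
#' classical spurious-correlation problem of constant-sum data. This
#' diagnostic quantifies the phenomenon for a given table.
#'
#' @param X positive numeric matrix or complete [composition_matrix()].
#' @return list with elements
#'   \item{cov_rowsums}{per-part row sums of the covariance matrix of the
#'     closed data (0 up to rounding)}
#'   \item{cor}{correlation matrix of the closed data}
#'   \item{min_offdiag_cor, max_offdiag_cor}{per-part extreme off-diagonal
#'     correlations}
#'   \item{n_parts_max_negative}{number of parts whose largest off-diagonal
#'     correlation is negative}
#'   \item{n_parts_any_negative}{number of parts with at least one negative
#'     correlation to another part}
#' @export
closure_bias_diagnostic <- function(X) {
  v <- comp_values(X, "closure-bias diagnostic")
  Xc <- close_composition(v, 1)
  S <- stats::cov(Xc)
  C <- stats::cor(Xc)
  off <- C
  diag(off) <- NA_real_
  mx <- apply(off, 1, max, na.rm = TRUE)
  mn <- apply(off, 1, min, na.rm = TRUE)
  list(cov_rowsums = rowSums(S),
       cor = C,
       min_offdiag_cor = mn,
       max_offdiag_cor = mx,
       n_parts_max_negative = sum(mx < 0),
       n_parts_any_negative = sum(mn < 0))
}
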