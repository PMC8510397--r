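#' Principal component analysis of a coordinate representation
#'
#' Eigen-decomposition of the sample covariance matrix of an (already
#' pre-processed) coordinate representation. For the z-scored regimes
#' (`scale`, `log_scale`, `closed_scale`) the covariance of the input
#' equals the correlation matrix of the underlying variables; for the
#' log-ratio regimes (`clr`, `ilr`, `ilr_var`) the coordinates are used as
#' they are — standardizing them would destroy the Aitchison geometry.
#' Components are ordered by explained variance and the sign of each
#' loading vector is fixed so its largest-magnitude entry is positive,
#' making biplot orientation deterministic.
#'
#' Because clr rows sum to zero, clr input has one exactly-zero eigenvalue;
#' the non-zero part of the spectrum equals the spectrum of any pivot-ilr
#' representation of the same compositions (the two are isometric).
#'
#' @param R a [coordinate_matrix()] or numeric matrix with at least 3 rows.
#' @return A `pca_result`: list with `loadings` (m x k, orthonormal
#'   columns), `scores` (n x k), `explained` (proportions, non-increasing,
#'   summing to 1), `center` (column means removed), `representation`.
#' @export
pca_coordinates <- function(R) {
  repr <- if (inherits(R, "coordinate_matrix")) R$representation else "raw"
  X <- coord_values(R)
  if (nrow(X) < 3L) stop("PCA needs at least 3 samples")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  S <- stats::cov(Xc)
  tot <- sum(diag(S))
  if (!is.finite(tot) || tot <= 1e-12)
    stop("degenerate input: total variance is zero")
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  L <- e$vectors
  for (k in seq_len(ncol(L))) {           # deterministic sign convention
    i <- which.max(abs(L[, k]))
    if (L[i, k] < 0) L[, k] <- -L[, k]
  }
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("PC", seq_len(ncol(L)))
  scores <- Xc %*% L
  colnames(scores) <- colnames(L)
  structure(list(loadings = L, scores = scores,
                 explained = ev / sum(ev), center = ctr,
                 representation = repr),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result (%s): %d components\n",
              x$representation, length(x$explained)))
  cat("explained (%):",
      paste(sprintf("%.1f", 100 * x$explained[seq_len(min(5, length(x$explained)))]),
            collapse = " "), "...\n")
  invisible(x)
}

#' Cumulative explained variance across pre-processing regimes
#'
#' Runs [pca_coordinates()] on each requested representation of the same
#' complete composition table and tabulates the cumulative percentage of
#' variance explained by the first k components. The curves reach 100% at
#' k = m (m = D, or D - 1 for the pivot representations) and are the
#' standard way to compare how much structure each pre-processing choice
#' concentrates in few components.
#'
#' @param X complete [composition_matrix()] or positive matrix.
#' @param specs character vector of representation tags (see
#'   [preprocess()]).
#' @param y class labels, required when `"ilr_var"` is among `specs`.
#' @return data.frame with columns `representation`, `k`, `explained_pct`
#'   (per component) and `cumulative_pct`.
#' @export
explained_variance_table <- function(X, specs, y = NULL) {
  out <- lapply(specs, function(sp) {
    p <- pca_coordinates(preprocess(X, sp, y = y))
    k <- seq_along(p$explained)
    data.frame(representation = normalize_repr(sp), k = k,
               explained_pct = 100 * p$explained,
               cumulative_pct = 100 * cumsum(p$explained))
  })
  do.call(rbind, out)
}

#' Biplot layout for the first two principal components
#'
#' Returns plotting-ready coordinates: sample scores on PC1/PC2 and one
#' loading arrow per variable. Loading vectors are rows of an orthonormal
#' matrix, so every arrow has length at most 1. For clr input the cosine of
#' the angle between two arrows approximates the correlation between the
#' corresponding clr coordinates, which is what makes the compositional
#' biplot interpretable (and what the closure-biased non-compositional
#' biplots distort).
#'
#' @param p a `pca_result` with at least 2 components.
#' @param labels optional class labels attached to the scores.
#' @return list with `scores` (data.frame: PC1, PC2, label), `arrows`
#'   (data.frame: part, PC1, PC2, length), and `captions` (axis labels with
#'   explained percentages).
#' @export
biplot_layout <- function(p, labels = NULL) {
  stopifnot(inherits(p, "pca_result"))
  if (length(p$explained) < 2L) stop("biplot needs at least 2 components")
  sc <- data.frame(PC1 = p$scores[, 1], PC2 = p$scores[, 2])
  if (!is.null(labels)) sc$label <- labels
  part_names <- rownames(p$loadings) %||%
    paste0("var", seq_len(nrow(p$loadings)))
  ar <- data.frame(part = part_names,
                   PC1 = p$loadings[, 1], PC2 = p$loadings[, 2])
  ar$length <- sqrt(ar$PC1^2 + ar$PC2^2)
  caps <- sprintf("PC%d (%.1f%%)", 1:2, 100 * p$explained[1:2])
  list(scores = sc, arrows = ar, captions = caps)
}

#' Draw a biplot with ggplot2
#'
#' Convenience plot of a [biplot_layout()]; requires ggplot2.
#'
#' @inheritParams biplot_layout
#' @param arrow_scale multiplier applied to the loading arrows so they are
#'   visible on the score scale.
#' @return a ggplot object.
#' @export
plot_biplot <- function(p, labels = NULL, arrow_scale = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_biplot requires the ggplot2 package")
  lay <- biplot_layout(p, labels)
  if (is.null(arrow_scale))
    arrow_scale <- 0.8 * max(abs(unlist(lay$scores[, 1:2])))
  ar <- lay$arrows
  ar$PC1 <- ar$PC1 * arrow_scale
  ar$PC2 <- ar$PC2 * arrow_scale
  gg <- ggplot2::ggplot(lay$scores, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  gg <- if ("label" %in% names(lay$scores)) {
    gg + ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.7)
  } else gg + ggplot2::geom_point(alpha = 0.7)
  gg +
    ggplot2::geom_segment(data = ar,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1, yend = .data$PC2),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey30") +
    ggplot2::geom_text(data = ar,
      ggplot2::aes(label = .data$part), vjust = -0.4, size = 3) +
    ggplot2::labs(x = lay$captions[1], y = lay$captions[2]) +
    ggplot2::theme_minimal()
}
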