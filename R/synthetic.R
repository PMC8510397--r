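#' Specification of a synthetic compositional dataset
#'
#' Defines a logistic-normal generator on the simplex: each class has a
#' mean vector (length D-1) and covariance in pivot-coordinate space;
#' samples are drawn there, mapped back to compositions, and multiplied by
#' a lognormal per-sample total so the raw table carries an arbitrary
#' "size effect" that log-ratio methods must (and do) ignore.
#'
#' @param parts character vector of part names (length D >= 3), or an
#'   integer D.
#' @param class_means named list of per-class mean vectors, each of length
#'   D - 1 (pivot-coordinate space).
#' @param class_cov a single (D-1) x (D-1) symmetric positive-definite
#'   matrix shared by all classes, a scalar (isotropic sd), or a named
#'   list of per-class matrices.
#' @param n_per_class named integer vector of samples per class.
#' @param total_meanlog,total_sdlog parameters of the lognormal row-total
#'   distribution (log mg/kg).
#' @return a `generator_spec` list, validated.
#' @export
generator_spec <- function(parts, class_means, class_cov = 0.5,
                           n_per_class, total_meanlog = log(1000),
                           total_sdlog = 0.5) {
  if (is.numeric(parts) && length(parts) == 1L)
    parts <- paste0("part", seq_len(parts))
  D <- length(parts)
  if (D < 3L) stop("need at least 3 parts")
  if (is.null(names(class_means)))
    names(class_means) <- paste0("class", seq_along(class_means))
  classes <- names(class_means)
  for (cl in classes)
    if (length(class_means[[cl]]) != D - 1L)
      stop("class mean for '", cl, "' must have length D - 1 = ", D - 1L)
  covs <- normalize_covs(class_cov, classes, D - 1L)
  n_per_class <- rep_len(as.integer(n_per_class), length(classes))
  names(n_per_class) <- classes
  if (any(n_per_class < 1L)) stop("samples per class must be >= 1")
  if (!is.numeric(total_sdlog) || total_sdlog < 0)
    stop("'total_sdlog' must be non-negative")
  structure(list(parts = parts, class_means = class_means, class_cov = covs,
                 n_per_class = n_per_class, total_meanlog = total_meanlog,
                 total_sdlog = total_sdlog),
            class = "generator_spec")
}

normalize_covs <- function(class_cov, classes, m) {
  expand1 <- function(cv) {
    if (is.numeric(cv) && length(cv) == 1L) cv <- diag(cv^2, m)
    cv <- as.matrix(cv)
    if (!identical(dim(cv), c(m, m)))
      stop("covariance must be ", m, " x ", m)
    if (max(abs(cv - t(cv))) > 1e-8) stop("covariance must be symmetric")
    if (min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("covariance must be positive-definite")
    cv
  }
  if (is.list(class_cov) && !is.matrix(class_cov)) {
    out <- lapply(class_cov, expand1)
    if (is.null(names(out))) names(out) <- classes
    out[classes]
  } else {
    cv <- expand1(class_cov)
    stats::setNames(rep(list(cv), length(classes)), classes)
  }
}

#' Generate a synthetic composition table
#'
#' Draws `n_per_class` pivot-coordinate vectors per class from the normal
#' distribution of the spec, maps them to the simplex with
#' [pivot_ilr_inverse()], and multiplies each row by a lognormal total.
#' The output is strictly positive by construction.
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed.
#' @return a [composition_matrix()] with class labels; attribute `"ilr"`
#'   holds the latent pivot coordinates.
#' @export
generate_composition <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  D <- length(spec$parts)
  with_seed(seed, {
    rows <- list(); labs <- list(); zs <- list()
    for (cl in names(spec$class_means)) {
      n <- spec$n_per_class[[cl]]
      Z <- MASS::mvrnorm(n, mu = spec$class_means[[cl]],
                         Sigma = spec$class_cov[[cl]])
      Z <- matrix(Z, nrow = n)
      Xc <- pivot_ilr_inverse(Z, kappa = 1)
      tot <- stats::rlnorm(n, spec$total_meanlog, spec$total_sdlog)
      rows[[cl]] <- Xc * tot
      labs[[cl]] <- rep(cl, n)
      zs[[cl]] <- Z
    }
    values <- do.call(rbind, rows)
    colnames(values) <- spec$parts
    out <- composition_matrix(values, labels = unlist(labs),
                              samples = paste0("s", seq_len(nrow(values))))
    attr(out, "ilr") <- do.call(rbind, zs)
    out
  })
}

#' Adulterate a fraction of the samples towards a contaminant
#'
#' Replaces selected rows by their perturbation towards a contaminant
#' composition inside the simplex: the component-wise power combination
#' `close(x^(1-alpha) * c^alpha)`, rescaled to the row's original total so
#' the size effect is preserved. `alpha` near 0 leaves the sample almost
#' unchanged; near 1 it approaches the contaminant profile. Labels of
#' adulterated rows get the suffix `"_adulterated"`. Mass-balance mixing
#' (`(1-alpha) * close(x) + alpha * close(c)`) is available via
#' `mode = "mass_balance"`.
#'
#' @param X a complete [composition_matrix()].
#' @param contaminant positive vector of length D: the contaminant profile.
#' @param alpha perturbation strength, strictly inside (0, 1).
#' @param fraction fraction of rows to adulterate (chosen at random).
#' @param rows explicit row indices to adulterate (overrides `fraction`).
#' @param mode `"power"` (Aitchison perturbation, default) or
#'   `"mass_balance"`.
#' @param seed integer seed for the row selection.
#' @return a [composition_matrix()]; attribute `"adulterated_rows"` lists
#'   the modified row indices.
#' @export
apply_adulteration <- function(X, contaminant, alpha, fraction = 1,
                               rows = NULL, mode = c("power", "mass_balance"),
                               seed = 1L) {
  mode <- match.arg(mode)
  X <- as_composition(X)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly inside (0, 1)")
  v <- comp_values(X, "adulteration")
  cc <- close_composition(as.numeric(contaminant), 1)
  if (length(cc) != ncol(v)) stop("'contaminant' must have length D")
  n <- nrow(v)
  if (is.null(rows)) {
    nsel <- round(fraction * n)
    rows <- if (nsel >= n) seq_len(n) else
      with_seed(seed, sort(sample.int(n, nsel)))
  }
  tot <- rowSums(v[rows, , drop = FALSE])
  base <- close_composition(v[rows, , drop = FALSE], 1)
  mixed <- if (mode == "power") {
    close_composition(sweep(base^(1 - alpha), 2, cc^alpha, "*"), 1)
  } else {
    (1 - alpha) * base + alpha * matrix(cc, length(rows), ncol(v), byrow = TRUE)
  }
  v[rows, ] <- mixed * tot
  labels <- X$labels
  if (!is.null(labels)) {
    labels <- as.character(labels)
    labels[rows] <- paste0(labels[rows], "_adulterated")
  }
  out <- composition_matrix(v, parts = X$parts, samples = X$samples,
                            labels = labels,
                            detection_limits = X$detection_limits)
  attr(out, "adulterated_rows") <- rows
  out
}

#' Left-censor a table below per-part detection limits
#'
#' Sets each part's detection limit at the empirical quantile of that part
#' matching the target overall censoring rate, masks every entry strictly
#' below its limit, and keeps the uncensored truth so imputation quality
#' can be scored against it.
#'
#' @param X a complete [composition_matrix()].
#' @param target_rate desired overall fraction of masked cells, in
#'   `[0, 1)`.
#' @param seed kept for interface symmetry; the construction is
#'   deterministic.
#' @return list with `data` (the masked [composition_matrix()], carrying
#'   the detection limits), `truth` (the uncensored value matrix), `mask`
#'   and `detection_limits`.
#' @export
censor_below_dl <- function(X, target_rate, seed = 1L) {
  X <- as_composition(X)
  if (!is.numeric(target_rate) || target_rate < 0 || target_rate >= 1)
    stop("'target_rate' must lie in [0, 1)")
  v <- comp_values(X, "censoring")
  if (target_rate == 0) {
    return(list(data = X, truth = v,
                mask = matrix(FALSE, nrow(v), ncol(v)),
                detection_limits = NULL))
  }
  dl <- apply(v, 2, stats::quantile, probs = target_rate, names = FALSE)
  names(dl) <- X$parts
  mask <- sweep(v, 2, dl, "<")
  masked <- v
  masked[mask] <- NA_real_
  data <- composition_matrix(masked, parts = X$parts, samples = X$samples,
                             labels = X$labels, mask = mask,
                             detection_limits = dl)
  list(data = data, truth = v, mask = mask, detection_limits = dl)
}

#' Honey-like study conditions
#'
#' A fixed desk-scale emulation of a mineral-element authentication
#' dataset: 12 parts named after the honey elements (Al, B, Ba, Ca, Fe, K,
#' Mg, Mn, Na, P, Sr, Zn), six pure classes of 34/34/34/33/33/33 samples
#' (201 in total), one syrup class of 45 samples with its own centre, and
#' 183 adulterated samples obtained by perturbing extra pure draws towards
#' the syrup centre with `alpha = 0.35`. Class centres are drawn once from
#' N(0, 0.8^2) in pivot-coordinate space under the given seed; within-class
#' sd is 0.5; row totals are lognormal(log 1000, 0.5). 7.75% of the cells
#' are then left-censored below per-part detection limits.
#'
#' @param seed integer seed fixing centres, draws and censoring.
#' @param censor_rate overall fraction of censored cells.
#' @return list with `data` (masked [composition_matrix()] with 13
#'   classes), `truth`, `mask`, `detection_limits`, and `label3` (the
#'   3-class target: honey / syrup / adulterated).
#' @export
simulate_honey_like <- function(seed = 1L, censor_rate = 0.0775) {
  parts <- c("Al", "B", "Ba", "Ca", "Fe", "K", "Mg", "Mn", "Na", "P",
             "Sr", "Zn")
  D <- length(parts)
  pure <- c(AC = 34L, CA = 34L, JU = 34L, LD = 33L, SS = 33L, RP = 33L)
  centres <- with_seed(seed, {
    cs <- lapply(seq_len(7), function(i) stats::rnorm(D - 1L, 0, 0.8))
    names(cs) <- c(names(pure), "Sy")
    cs
  })
  spec_pure <- generator_spec(parts, centres[names(pure)], class_cov = 0.5,
                              n_per_class = pure,
                              total_meanlog = log(1000), total_sdlog = 0.5)
  spec_syrup <- generator_spec(parts, centres["Sy"], class_cov = 0.5,
                               n_per_class = c(Sy = 45L),
                               total_meanlog = log(1000), total_sdlog = 0.5)
  extra_n <- c(AC = 31L, CA = 31L, JU = 31L, LD = 30L, SS = 30L, RP = 30L)
  spec_extra <- generator_spec(parts, centres[names(pure)], class_cov = 0.5,
                               n_per_class = extra_n,
                               total_meanlog = log(1000), total_sdlog = 0.5)
  Xp <- generate_composition(spec_pure, seed = seed + 1L)
  Xs <- generate_composition(spec_syrup, seed = seed + 2L)
  Xe <- generate_composition(spec_extra, seed = seed + 3L)
  syrup_centre <- drop(pivot_ilr_inverse(matrix(centres[["Sy"]], 1), kappa = 1))
  Xa <- apply_adulteration(Xe, syrup_centre, alpha = 0.35, fraction = 1,
                           seed = seed + 4L)
  values <- rbind(Xp$values, Xs$values, Xa$values)
  labels <- c(as.character(Xp$labels), as.character(Xs$labels),
              as.character(Xa$labels))
  full <- composition_matrix(values, parts = parts,
                             samples = paste0("s", seq_len(nrow(values))),
                             labels = labels)
  cen <- censor_below_dl(full, censor_rate, seed = seed)
  label3 <- ifelse(labels == "Sy", "syrup",
                   ifelse(grepl("_adulterated$", labels), "adulterated",
                          "honey"))
  c(cen, list(label3 = factor(label3)))
}

#' Size-effect study conditions
#'
#' Three classes whose signal lives purely in the log-ratios (separated
#' pivot-coordinate centres) while the row totals fluctuate over orders of
#' magnitude (lognormal sd 1.5 on the log scale). Raw-concentration
#' classifiers are dominated by the irrelevant totals; log-ratio
#' representations remove them entirely. Used by the classification
#' benchmark.
#'
#' @param n_per_class samples per class (3 classes).
#' @param D number of parts.
#' @param separation distance scale of the class centres in
#'   pivot-coordinate space.
#' @param seed integer seed for the class centres.
#' @return a [generator_spec()].
#' @export
size_effect_spec <- function(n_per_class = 200L, D = 10L, separation = 1.2,
                             seed = 7L) {
  centres <- with_seed(seed, {
    cs <- lapply(1:3, function(i) stats::rnorm(D - 1L, 0, separation / sqrt(2)))
    names(cs) <- c("A", "B", "C")
    cs
  })
  generator_spec(D, centres, class_cov = 0.5,
                 n_per_class = rep(n_per_class, 3),
                 total_meanlog = log(1000), total_sdlog = 1.5)
}
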