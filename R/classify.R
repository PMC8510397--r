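#' Stratified folds for repeated k-fold cross-validation
#'
#' Assigns each sample to one of `k` folds, separately per class, so each
#' fold's class proportions match the overall ones within one sample; the
#' whole assignment is repeated `repeats` times. If some class has fewer
#' than `k` members, `k` is reduced to the smallest class size with a
#' warning.
#'
#' @param y class labels (>= 2 classes).
#' @param k number of folds.
#' @param repeats number of independent repetitions.
#' @param seed integer seed; the same seed reproduces the assignment.
#' @return list with `folds` (list of `repeats` integer vectors of fold
#'   ids, one per sample) and `k` (the possibly reduced fold count).
#' @export
make_folds <- function(y, k = 10L, repeats = 5L, seed = 1L) {
  y <- factor(y)
  if (nlevels(y) < 2L) stop("cross-validation needs at least 2 classes")
  sizes <- table(y)
  if (min(sizes) < k) {
    k_new <- max(2L, as.integer(min(sizes)))
    warning("smallest class has ", min(sizes), " members; reducing k from ",
            k, " to ", k_new)
    k <- k_new
  }
  with_seed(seed, {
    folds <- lapply(seq_len(repeats), function(r) {
      fold <- integer(length(y))
      for (cl in levels(y)) {
        idx <- which(y == cl)
        # balanced counts per fold; which folds receive an extra sample is
        # randomized by relabelling
        ids <- rep_len(seq_len(k), length(idx))
        ids <- sample.int(k)[ids]
        fold[sample(idx)] <- ids
      }
      fold
    })
    list(folds = folds, k = k)
  })
}

#' Train a classifier on a coordinate representation
#'
#' Thin common interface over the three classifiers of the benchmark:
#' \describe{
#'   \item{lda}{linear discriminant analysis (normality-based linear
#'     boundaries). clr coordinates are rank-deficient (rows sum to 0), so
#'     for LDA they are mapped to an internal pivot basis first — an
#'     isometry, hence decision-equivalent.}
#'   \item{knn}{k-nearest-neighbour vote; `k` is either supplied via
#'     `params$k` or tuned by an inner 5-fold cross-validation over
#'     `1, 3, ..., 15` on the training data.}
#'   \item{ann}{the dense feed-forward network of [mlp_classifier()].}
#' }
#'
#' @param R training coordinates ([coordinate_matrix()] or matrix).
#' @param y training class labels (>= 2 classes).
#' @param method `"lda"`, `"knn"` or `"ann"`.
#' @param params list of method parameters (`k` for knn; any
#'   [mlp_classifier()] argument for ann).
#' @param seed integer seed for the stochastic parts (knn tuning folds,
#'   network training).
#' @return a `coda_classifier` with a `predict` method taking new
#'   coordinates.
#' @export
train_classifier <- function(R, y, method = c("lda", "knn", "ann"),
                             params = list(), seed = 1L) {
  method <- match.arg(method)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("training data must contain at least 2 classes")
  repr <- if (inherits(R, "coordinate_matrix")) R$representation else "raw"
  X <- coord_values(R)
  basis <- NULL
  if (method == "lda" && repr == "clr") {
    basis <- pivot_basis(ncol(X))   # isometric full-rank coordinates
    X <- X %*% basis
  }
  model <- switch(method,
    lda = MASS::lda(X, grouping = y),
    knn = {
      k <- params$k %||% tune_knn_k(X, y, seed = seed)
      list(train = X, y = y, k = k)
    },
    ann = {
      args <- params
      args$x <- X; args$y <- y
      if (is.null(args$seed)) args$seed <- seed
      do.call(mlp_classifier, args)
    })
  structure(list(method = method, model = model, basis = basis,
                 levels = levels(y)),
            class = "coda_classifier")
}

tune_knn_k <- function(X, y, grid = c(1L, 3L, 5L, 7L, 9L, 11L, 13L, 15L),
                       folds = 5L, seed = 1L) {
  grid <- grid[grid < nrow(X)]
  if (!length(grid)) return(1L)
  assign_k <- min(folds, min(table(y)))
  if (assign_k < 2L) return(grid[1])
  f <- make_folds(y, k = assign_k, repeats = 1L, seed = seed)$folds[[1]]
  err <- numeric(length(grid))
  for (fi in seq_len(max(f))) {
    tr <- f != fi
    if (nlevels(droplevels(y[tr])) < 2L) next
    for (gi in seq_along(grid)) {
      pred <- class::knn(X[tr, , drop = FALSE], X[!tr, , drop = FALSE],
                         y[tr], k = grid[gi])
      err[gi] <- err[gi] + sum(pred != y[!tr])
    }
  }
  grid[which.min(err)]   # ties favour the smaller k
}

#' @export
predict.coda_classifier <- function(object, newdata, ...) {
  X <- coord_values(newdata)
  if (!is.null(object$basis)) X <- X %*% object$basis
  out <- switch(object$method,
    lda = stats::predict(object$model, X)$class,
    knn = class::knn(object$model$train, X, object$model$y,
                     k = object$model$k),
    ann = stats::predict(object$model, X))
  factor(as.character(out), levels = object$levels)
}

#' Cross-validated misclassification for one pipeline cell
#'
#' Runs the full pipeline — zero replacement, coordinate representation,
#' classifier — under stratified k-fold cross-validation repeated
#' `repeats` times. Every data-dependent quantity is learned on the
#' training fold only and then applied to the held-out fold: proxy
#' detection limits and per-part minima, the censored-PLS fits, z-score
#' centre/scale, the `ilr_var` part ordering, the tuned knn `k`, and the
#' network weights.
#'
#' @param X a [composition_matrix()]; masked cells are allowed (the
#'   replacement runs inside the loop).
#' @param y class labels; defaults to the labels carried by `X`.
#' @param replacement `"none"`, `"const"`, `"dl23"`, `"unif"` or
#'   `"bdls_pls"`.
#' @param representation a tag accepted by [preprocess()].
#' @param classifier `"lda"`, `"knn"` or `"ann"`.
#' @param k,repeats folds and repetitions of the cross-validation.
#' @param seed integer seed controlling folds, draws and training.
#' @param classifier_params passed to [train_classifier()].
#' @param audit when `TRUE`, attach attribute `"fit_rows"`: the list of
#'   row indices seen by the fitting steps of each fold, so leakage of
#'   test rows into any fit can be checked.
#' @return list with `mean_rate` (mean of per-repeat means), `records`
#'   (data.frame: replacement, representation, classifier, repeat, fold,
#'   rate) and `k`.
#' @export
cv_misclassification <- function(X, y = NULL, replacement = "none",
                                 representation = "clr",
                                 classifier = "lda", k = 10L, repeats = 5L,
                                 seed = 1L, classifier_params = list(),
                                 audit = FALSE) {
  X <- as_composition(X)
  if (is.null(y)) y <- X$labels
  if (is.null(y)) stop("class labels are required")
  y <- factor(y)
  representation <- normalize_repr(representation)
  fm <- make_folds(y, k = k, repeats = repeats, seed = seed)
  rec <- list()
  audit_rows <- list()
  for (r in seq_len(repeats)) {
    fold <- fm$folds[[r]]
    for (f in seq_len(fm$k)) {
      te <- which(fold == f)
      tr <- which(fold != f)
      cell_seed <- (seed + 97L * r + f) %% .Machine$integer.max
      fit_rep <- fit_replacement(X[tr], replacement, seed = cell_seed)
      Xtr <- fit_rep$train_completed %||% apply_replacement(fit_rep, X[tr])
      Xte <- apply_replacement(fit_rep, X[te])
      prep <- preprocess_fit(Xtr, representation, y = y[tr])
      Rtr <- preprocess_apply(prep, Xtr)
      Rte <- preprocess_apply(prep, Xte)
      clf <- train_classifier(Rtr, y[tr], method = classifier,
                              params = classifier_params, seed = cell_seed)
      pred <- stats::predict(clf, Rte)
      rate <- mean(pred != y[te])
      rec[[length(rec) + 1L]] <- data.frame(
        replacement = replacement, representation = representation,
        classifier = classifier, rep = r, fold = f, rate = rate,
        seed = seed)
      if (audit) audit_rows[[length(audit_rows) + 1L]] <-
        list(rep = r, fold = f, fit_rows = tr, test_rows = te)
    }
  }
  records <- do.call(rbind, rec)
  per_rep <- tapply(records$rate, records$rep, mean)
  out <- list(mean_rate = mean(per_rep), records = records, k = fm$k)
  if (audit) attr(out, "fit_rows") <- audit_rows
  out
}

#' Benchmark grid over replacement x representation x classifier
#'
#' Evaluates [cv_misclassification()] on the full cross product of the
#' supplied tags, sharing the fold assignment across cells so the methods
#' are compared on identical resampling splits. A failing cell is recorded
#' with the failure reason and the grid continues.
#'
#' @inheritParams cv_misclassification
#' @param replacements,representations,classifiers character vectors of
#'   tags defining the grid.
#' @return list with `records` (tidy per-fold data.frame), `summary`
#'   (mean and sd of the misclassification rate per cell) and `failures`
#'   (data.frame of skipped cells, if any).
#' @export
benchmark_grid <- function(X, y = NULL, replacements = "none",
                           representations = c("raw", "clr"),
                           classifiers = "lda", k = 10L, repeats = 5L,
                           seed = 1L, classifier_params = list()) {
  stopifnot(length(replacements) > 0, length(representations) > 0,
            length(classifiers) > 0)
  cells <- expand.grid(replacement = replacements,
                       representation = representations,
                       classifier = classifiers,
                       stringsAsFactors = FALSE)
  recs <- list(); fails <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    res <- tryCatch(
      cv_misclassification(X, y, replacement = cell$replacement,
                           representation = cell$representation,
                           classifier = cell$classifier, k = k,
                           repeats = repeats, seed = seed,
                           classifier_params = classifier_params),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        replacement = cell$replacement, representation = cell$representation,
        classifier = cell$classifier, reason = conditionMessage(res))
    } else {
      recs[[length(recs) + 1L]] <- res$records
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else NULL
  list(records = records,
       summary = if (!is.null(records)) summarize_benchmark(records),
       failures = if (length(fails)) do.call(rbind, fails))
}

#' Summarize a benchmark table
#'
#' Aggregates per-fold misclassification records to one row per
#' (replacement, representation, classifier) cell: the mean over folds of
#' each repetition, averaged over repetitions, with the standard deviation
#' of the per-repetition means.
#'
#' @param records the `records` element of [benchmark_grid()] or
#'   [cv_misclassification()].
#' @return data.frame with columns `replacement`, `representation`,
#'   `classifier`, `mean_rate`, `sd_rate`.
#' @export
summarize_benchmark <- function(records) {
  rep_means <- stats::aggregate(rate ~ replacement + representation +
                                  classifier + rep, data = records, FUN = mean)
  out <- stats::aggregate(rate ~ replacement + representation + classifier,
                          data = rep_means,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  data.frame(out[, 1:3],
             mean_rate = out$rate[, "mean"],
             sd_rate = out$rate[, "sd"])
}
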