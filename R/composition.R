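#' Compositional concentration table
#'
#' Container for an `n x D` table of strictly positive concentrations
#' (samples in rows, chemical parts in columns, typically mg/kg), together
#' with sample ids, a class label per sample, a logical mask flagging
#' non-detects / missing entries, and optional per-part detection limits.
#' Masked cells hold `NA` in `values` and must be completed with one of the
#' [replacement strategies][replace_const] before any log-ratio operation.
#'
#' @param values numeric matrix, `n x D`; masked cells may be `NA` or 0
#'   (both are recorded in the mask), all other cells strictly positive.
#' @param parts character vector of `D` unique part (element) names;
#'   defaults to the column names of `values`.
#' @param samples character vector of `n` sample ids; defaults to row names.
#' @param labels class label per sample (coerced to factor), or `NULL`.
#' @param mask logical `n x D` matrix flagging non-detect / missing cells.
#'   Defaults to `is.na(values) | values == 0`.
#' @param detection_limits optional named numeric vector of `D` strictly
#'   positive per-part detection limits (mg/kg).
#'
#' @return An object of class `composition_matrix`.
#' @seealso [close_composition()], [clr_transform()], [pivot_ilr()],
#'   [replace_const()], [read_composition_csv()]
#' @export
composition_matrix <- function(values, parts = colnames(values),
                               samples = rownames(values), labels = NULL,
                               mask = NULL, detection_limits = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  D <- ncol(values)
  if (D < 2L) stop("a composition needs at least 2 parts, got ", D)
  if (is.null(parts)) parts <- paste0("part", seq_len(D))
  parts <- as.character(parts)
  if (length(parts) != D) stop("'parts' must have length ", D)
  if (anyDuplicated(parts)) stop("part names must be unique")
  if (is.null(samples)) samples <- paste0("s", seq_len(n))
  samples <- as.character(samples)
  if (length(samples) != n) stop("'samples' must have length ", n)
  if (is.null(mask)) {
    mask <- is.na(values) | values == 0
  } else {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(values)))
      stop("'mask' must have the same shape as 'values'")
    storage.mode(mask) <- "logical"
    mask <- mask | is.na(values)
  }
  bad <- which(!mask & values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-positive unmasked entry at sample '%s', part '%s': %g",
      samples[bad[1, 1]], parts[bad[1, 2]], values[bad[1, 1], bad[1, 2]]))
  }
  values[mask] <- NA_real_  # placeholder; never enters a log
  dimnames(values) <- list(samples, parts)
  dimnames(mask) <- dimnames(values)
  if (!is.null(labels)) {
    if (length(labels) != n) stop("'labels' must have length ", n)
    labels <- factor(labels)
  }
  if (!is.null(detection_limits)) {
    detection_limits <- check_dl(detection_limits, parts)
  }
  structure(
    list(values = values, parts = parts, samples = samples,
         labels = labels, mask = mask, detection_limits = detection_limits),
    class = "composition_matrix")
}

check_dl <- function(dl, parts) {
  dl <- unlist(dl)
  if (!is.null(names(dl))) {
    missing <- setdiff(parts, names(dl))
    if (length(missing))
      stop("detection limits missing for parts: ",
           paste(missing, collapse = ", "))
    dl <- dl[parts]
  } else {
    if (length(dl) != length(parts))
      stop("'detection_limits' must have length ", length(parts))
    names(dl) <- parts
  }
  if (any(!is.finite(dl) | dl <= 0))
    stop("detection limits must be strictly positive")
  dl
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat(sprintf("composition_matrix: %d samples x %d parts\n",
              nrow(x$values), ncol(x$values)))
  cat("parts:", paste(x$parts, collapse = ", "), "\n")
  if (!is.null(x$labels))
    cat("classes:", paste(levels(x$labels), collapse = ", "), "\n")
  nmask <- sum(x$mask)
  cat(sprintf("masked (non-detect/missing) cells: %d (%.2f%%)\n",
              nmask, 100 * nmask / length(x$mask)))
  if (!is.null(x$detection_limits)) cat("detection limits: supplied\n")
  invisible(x)
}

#' @export
dim.composition_matrix <- function(x) dim(x$values)

#' @export
as.matrix.composition_matrix <- function(x, ...) x$values

#' Subset samples of a composition_matrix
#' @param x a [composition_matrix()]
#' @param i row (sample) index
#' @param ... ignored
#' @return a `composition_matrix` with the selected samples
#' @export
`[.composition_matrix` <- function(x, i, ...) {
  composition_matrix(
    values = x$values[i, , drop = FALSE],
    parts = x$parts,
    samples = x$samples[i],
    labels = if (!is.null(x$labels)) x$labels[i],
    mask = x$mask[i, , drop = FALSE],
    detection_limits = x$detection_limits)
}

#' Is a composition free of masked entries?
#' @param x a [composition_matrix()]
#' @return `TRUE` when no cell is masked.
#' @export
is_complete <- function(x) {
  stopifnot(inherits(x, "composition_matrix"))
  !any(x$mask)
}

# Coerce a composition_matrix or bare matrix/vector to a complete positive
# matrix, refusing masked/invalid entries. Used by every log-ratio entry
# point, so zeros are rejected with a pointer to the replacement step.
comp_values <- function(x, what = "this operation") {
  if (inherits(x, "composition_matrix")) {
    if (any(x$mask))
      stop(what, " requires a complete composition: ",
           sum(x$mask), " masked (non-detect) entries present; ",
           "run a zero-replacement strategy first ",
           "(replace_const, replace_dl23, replace_unif, replace_bdls_pls)")
    return(x$values)
  }
  v <- x
  if (is.null(dim(v))) v <- matrix(as.numeric(v), nrow = 1)
  v <- as.matrix(v)
  storage.mode(v) <- "double"
  bad <- which(!is.finite(v) | v <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "%s requires strictly positive entries; offending cell [%d, %d] = %s",
      what, bad[1, 1], bad[1, 2], format(v[bad[1, 1], bad[1, 2]])))
  }
  v
}

#' Real-coordinate representation of compositions
#'
#' Light container tagging an `n x m` real matrix with the pre-processing
#' representation that produced it. `m = D` for all representations except
#' the pivot (ilr) ones, where `m = D - 1`; ilr variants also record the
#' part ordering used.
#'
#' @param values numeric `n x m` matrix.
#' @param representation one of `"raw"`, `"scale"`, `"log"`, `"log_scale"`,
#'   `"closed_scale"`, `"clr"`, `"ilr"`, `"ilr_var"`.
#' @param part_order permutation of the parts (ilr variants only).
#' @param column_names column names for `values`.
#' @return An object of class `coordinate_matrix`.
#' @export
coordinate_matrix <- function(values, representation,
                              part_order = NULL, column_names = colnames(values)) {
  values <- as.matrix(values)
  representation <- match.arg(representation, REPRESENTATIONS)
  if (!is.null(column_names)) colnames(values) <- column_names
  structure(list(values = values, representation = representation,
                 part_order = part_order, column_names = colnames(values)),
            class = "coordinate_matrix")
}

# canonical representation vocabulary (aliases accepted by normalize_repr)
REPRESENTATIONS <- c("raw", "scale", "log", "log_scale", "closed_scale",
                     "clr", "ilr", "ilr_var")

normalize_repr <- function(repr) {
  aliases <- c(standardized = "scale", log_standardized = "log_scale",
               closed_standardized = "closed_scale")
  if (repr %in% names(aliases)) repr <- aliases[[repr]]
  match.arg(repr, REPRESENTATIONS)
}

#' @export
print.coordinate_matrix <- function(x, ...) {
  cat(sprintf("coordinate_matrix (%s): %d x %d\n",
              x$representation, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.coordinate_matrix <- function(x) dim(x$values)

#' @export
as.matrix.coordinate_matrix <- function(x, ...) x$values

coord_values <- function(x) {
  if (inherits(x, "coordinate_matrix")) x$values else as.matrix(x)
}
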