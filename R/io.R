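#' Read a concentration table from CSV
#'
#' Reads a wide samples-by-parts CSV (UTF-8, header row, "." decimal) into
#' a [composition_matrix()]. Cells equal to a missing-value sentinel
#' (empty, `NA`, `ND`, `<LOD` by default) are masked as non-detects.
#' Literal zeros are rounded zeros — concentrations below the detection
#' limit — so they are masked too, with a warning. Negative values are a
#' hard error naming the offending cell.
#'
#' @param path CSV file path.
#' @param id_col name of the sample-id column, or `NULL` to auto-number.
#' @param class_col name of the class-label column, or `NULL`.
#' @param part_cols character vector of part columns; default: every
#'   column except `id_col` and `class_col`.
#' @param na_strings sentinels interpreted as non-detect/missing.
#' @param detection_limits optional named per-part limits.
#' @return a [composition_matrix()].
#' @export
read_composition_csv <- function(path, id_col = "sample",
                                 class_col = "class", part_cols = NULL,
                                 na_strings = c("", "NA", "ND", "<LOD"),
                                 detection_limits = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (!is.null(id_col) && !id_col %in% names(raw)) id_col <- NULL
  if (!is.null(class_col) && !class_col %in% names(raw)) class_col <- NULL
  if (is.null(part_cols))
    part_cols <- setdiff(names(raw), c(id_col, class_col))
  if (length(part_cols) < 2L)
    stop("need at least 2 part columns, found ", length(part_cols))
  missing_cols <- setdiff(part_cols, names(raw))
  if (length(missing_cols))
    stop("part columns not in file: ", paste(missing_cols, collapse = ", "))
  samples <- if (!is.null(id_col)) raw[[id_col]] else
    paste0("s", seq_len(nrow(raw)))
  labels <- if (!is.null(class_col)) raw[[class_col]] else NULL
  vals <- matrix(NA_real_, nrow(raw), length(part_cols),
                 dimnames = list(samples, part_cols))
  mask <- matrix(FALSE, nrow(raw), length(part_cols))
  for (j in seq_along(part_cols)) {
    cell <- trimws(raw[[part_cols[j]]])
    sentinel <- cell %in% na_strings | is.na(cell)
    num <- suppressWarnings(as.numeric(cell))
    bad <- !sentinel & is.na(num)
    if (any(bad))
      stop(sprintf("unparseable value '%s' at row %d, column '%s'",
                   cell[which(bad)[1]], which(bad)[1], part_cols[j]))
    neg <- !sentinel & !is.na(num) & num < 0
    if (any(neg))
      stop(sprintf("negative concentration %g at row %d, column '%s'",
                   num[which(neg)[1]], which(neg)[1], part_cols[j]))
    zero <- !sentinel & num == 0
    if (any(zero))
      warning(sum(zero), " zero value(s) in column '", part_cols[j],
              "' treated as non-detects (rounded zeros)")
    vals[, j] <- num
    mask[, j] <- sentinel | zero
  }
  composition_matrix(vals, parts = part_cols, samples = samples,
                     labels = labels, mask = mask,
                     detection_limits = detection_limits)
}

#' Write a composition table to CSV
#'
#' Serializes values with 17 significant digits, so a write/read round
#' trip reproduces every double bit-exactly. Masked cells are written as
#' `"ND"`.
#'
#' @param X a [composition_matrix()].
#' @param path output CSV path.
#' @param nd_string string written for masked cells.
#' @return `path`, invisibly.
#' @export
write_composition_csv <- function(X, path, nd_string = "ND") {
  stopifnot(inherits(X, "composition_matrix"))
  v <- X$values
  out <- matrix(sprintf("%.17g", v), nrow(v), ncol(v))
  out[X$mask] <- nd_string
  df <- data.frame(sample = X$samples, stringsAsFactors = FALSE)
  if (!is.null(X$labels)) df$class <- as.character(X$labels)
  for (j in seq_along(X$parts)) df[[X$parts[j]]] <- out[, j]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

HONEY_ELEMENTS <- c("Al", "B", "Ba", "Ca", "Fe", "K", "Mg", "Mn", "Na",
                    "P", "Sr", "Zn")

SAFFRON_ELEMENTS <- c("Li", "B", "Na", "Mg", "Al", "K", "Ca", "V", "Mn",
                      "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "As", "Rb",
                      "Sr", "Y", "Mo", "Cd", "Cs", "Ba", "Ce", "Pr",
                      "Nd", "Sm", "Gd", "Pb")

#' Load a deposited honey mineral-profile table
#'
#' Reads a locally fetched copy of the honey/syrup/adulterated-honey
#' mineral dataset (12 elements, mg/kg) and attaches the 3-class
#' authentication target (honey / syrup / adulterated) derived from the
#' subtype labels: labels starting `"Sy"` are syrup, labels starting with
#' `"A"` followed by a pure-honey code (AAC, ACA, AJU, ALD, ASS, ARP) are
#' adulterated, everything else is pure honey. Blind samples (label
#' `"blind"`) are excluded unless `include_blind = TRUE`. No download is
#' attempted.
#'
#' @param path CSV file path (user-fetched deposit or compatible table).
#' @param include_blind keep rows labelled `blind`.
#' @param class_col,id_col column names in the file.
#' @return a [composition_matrix()] with 12 parts; attribute `"label3"`
#'   holds the 3-class target.
#' @export
load_honey <- function(path, include_blind = FALSE, class_col = "class",
                       id_col = "sample") {
  X <- read_composition_csv(path, id_col = id_col, class_col = class_col,
                            part_cols = HONEY_ELEMENTS)
  labels <- as.character(X$labels)
  if (!include_blind) {
    keep <- !grepl("^blind", labels, ignore.case = TRUE)
    X <- X[which(keep)]
    labels <- labels[keep]
  }
  adulterated <- grepl("^A(AC|CA|JU|LD|SS|RP)", labels)
  syrup <- grepl("^Sy", labels, ignore.case = TRUE)
  attr(X, "label3") <- factor(ifelse(syrup, "syrup",
                                     ifelse(adulterated, "adulterated",
                                            "honey")))
  X
}

#' Load a deposited saffron trace-element table
#'
#' Reads a locally fetched copy of the saffron trace-element dataset (29
#' elements) with a binary geographic-origin label (Iran / Spain). No
#' download is attempted.
#'
#' @inheritParams load_honey
#' @return a [composition_matrix()] with 29 parts and the origin label.
#' @export
load_saffron <- function(path, class_col = "class", id_col = "sample") {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  X <- read_composition_csv(path, id_col = id_col, class_col = class_col,
                            part_cols = intersect(header, SAFFRON_ELEMENTS))
  if (length(X$parts) != 29L)
    stop("expected the 29 saffron elements, found ", length(X$parts))
  X
}
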