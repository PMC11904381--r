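# Canonical feature roster and the labeled patient-by-feature container that
# every stage of the pipeline exchanges.

#' Canonical feature names
#'
#' The 19 features used throughout the package, in their fixed column order:
#' demographics (age, sex), the complete blood count with differential, the
#' monocyte distribution width (MDW), C-reactive protein (CRP), and the
#' derived neutrophils-to-lymphocytes ratio (NLR). `sex` is coded 1 = male,
#' 0 = female.
#'
#' @return Character vector of length 19.
#' @export
canonical_features <- function() {
  c("age", "sex", "wbc", "neutrophils", "monocytes", "mdw", "crp",
    "lymphocytes", "eosinophils", "basophils", "rbc", "hgb", "hct",
    "mcv", "mch", "mchc", "rdw", "plt", "nlr")
}

#' Construct a feature table
#'
#' A `feature_table` is the universal exchange object between stages: an
#' n-by-19 numeric matrix in the canonical column order, a logical
#' missingness mask of the same shape (`TRUE` means the cell is missing;
#' missing cells hold `NA` in `values`), and a binary sepsis label per row.
#'
#' @param values Numeric matrix, columns named exactly
#'   [canonical_features()] in order. Masked cells must be `NA`.
#' @param mask Logical matrix of the same dimension (default: `is.na(values)`).
#' @param labels Integer vector of 0/1 sepsis labels, one per row.
#' @param ids Optional row identifiers (default `1:n`).
#' @return An object of class `feature_table` with elements `ids`, `columns`,
#'   `values`, `mask`, `labels`.
#' @export
feature_table <- function(values, mask = NULL, labels, ids = NULL) {
  values <- as.matrix(values)
  if (!identical(colnames(values), canonical_features())) {
    bad <- setdiff(colnames(values), canonical_features())
    mis <- setdiff(canonical_features(), colnames(values))
    stop("feature_table: columns must be the canonical roster in order",
         if (length(bad)) paste0("; unknown: ", paste(bad, collapse = ", ")),
         if (length(mis)) paste0("; missing: ", paste(mis, collapse = ", ")))
  }
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- is.na(values)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(values)))
    stop("feature_table: mask dimensions differ from values")
  colnames(mask) <- colnames(values)
  if (any(is.na(values) != mask))
    stop("feature_table: mask must be TRUE exactly where values are NA")
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stop("feature_table: one label per row required")
  if (!all(labels %in% c(0L, 1L)))
    stop("feature_table: labels must be 0 or 1")
  if (is.null(ids)) ids <- seq_len(nrow(values))
  structure(
    list(ids = ids, columns = colnames(values), values = values,
         mask = mask, labels = labels),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d patients x %d features; prevalence %.4f; %d masked cells\n",
              nrow(x$values), ncol(x$values),
              mean(x$labels), sum(x$mask)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

# Row subset preserving all components.
subset_rows <- function(table, idx) {
  feature_table(table$values[idx, , drop = FALSE],
                table$mask[idx, , drop = FALSE],
                table$labels[idx], table$ids[idx])
}

#' Write a feature table to CSV
#'
#' Columns are the canonical features followed by `sepsis`; missing cells are
#' written as the empty string; finite values are serialized at 17
#' significant digits so that a write/read round trip is bit-exact.
#'
#' @param table A [feature_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  cols <- c(table$columns, "sepsis")
  lines <- c(paste(cols, collapse = ","),
             vapply(seq_len(nrow(table$values)), function(i) {
               paste(c(fmt(table$values[i, ]), table$labels[i]), collapse = ",")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Inverse of [write_table()]. The header must contain exactly the canonical
#' feature columns plus the `sepsis` label column (any order; columns are
#' reordered canonically). Empty cells become masked entries. Unknown
#' columns, absent required columns and non-numeric cells are errors that
#' name the offending column (and row, for cell-level problems).
#'
#' @param path CSV file path.
#' @return A [feature_table()].
#' @export
read_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  want <- c(canonical_features(), "sepsis")
  extra <- setdiff(names(df), want)
  if (length(extra))
    stop("read_table: unrecognized column(s): ", paste(extra, collapse = ", "))
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols))
    stop("read_table: required column(s) absent: ",
         paste(missing_cols, collapse = ", "))
  parse_col <- function(nm) {
    raw <- df[[nm]]
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(out) & raw != "")
    if (length(bad))
      stop(sprintf("read_table: non-numeric cell at row %d, column '%s': '%s'",
                   bad[1], nm, raw[bad[1]]))
    out
  }
  vals <- vapply(canonical_features(), parse_col, numeric(nrow(df)))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, canonical_features()))
  lab_raw <- df[["sepsis"]]
  lab <- suppressWarnings(as.numeric(lab_raw))
  if (any(is.na(lab)))
    stop(sprintf("read_table: non-numeric label at row %d", which(is.na(lab))[1]))
  if (!all(lab %in% c(0, 1)))
    stop("read_table: 'sepsis' labels must be 0 or 1")
  feature_table(vals, labels = lab)
}
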