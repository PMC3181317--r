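#' Construct a two-group dataset of measured variables
#'
#' Bundles a samples x variables concentration matrix with a binary group
#' label per sample. This is the common input container for the univariate
#' screen, the per-group association networks and the differential network.
#'
#' @param values Numeric matrix (samples in rows, variables in columns).
#'   Column names are used as variable names when `variable_names` is `NULL`.
#' @param group_labels Vector with exactly two distinct values, one per row
#'   of `values`. The first level encountered (or the factor level order, if
#'   a factor is supplied) defines the reference group for all downstream
#'   comparisons.
#' @param variable_names Optional character vector of unique variable names.
#' @param n_dropped Number of rows removed upstream (e.g. for missingness);
#'   recorded for reporting only.
#'
#' @return An object of class `grouped_dataset`: a list with elements
#'   `values`, `variable_names`, `group_labels` (factor with two levels),
#'   `group_sizes` (named integer vector), and `n_dropped`.
#' @seealso [read_grouped_table()], [fit_group()], [build_differential_network()]
#' @export
grouped_dataset <- function(values, group_labels, variable_names = NULL,
                            n_dropped = 0L) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(variable_names)) {
    variable_names <- colnames(values)
  }
  if (is.null(variable_names)) {
    variable_names <- paste0("V", seq_len(ncol(values)))
  }
  if (anyDuplicated(variable_names)) {
    stop("variable names must be unique", call. = FALSE)
  }
  if (length(variable_names) != ncol(values)) {
    stop("length of `variable_names` must equal ncol(values)", call. = FALSE)
  }
  colnames(values) <- variable_names
  if (length(group_labels) != nrow(values)) {
    stop("`group_labels` must have one entry per row of `values`", call. = FALSE)
  }
  if (!is.factor(group_labels)) {
    group_labels <- factor(group_labels, levels = unique(as.character(group_labels)))
  }
  group_labels <- droplevels(group_labels)
  if (nlevels(group_labels) != 2L) {
    stop("expected exactly two groups, found ", nlevels(group_labels),
         ": ", paste(levels(group_labels), collapse = ", "), call. = FALSE)
  }
  sizes <- table(group_labels)
  if (any(sizes < 2L)) {
    stop("each group needs at least 2 samples (sizes: ",
         paste(sizes, collapse = ", "), ")", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("`values` must not contain missing entries; drop incomplete rows first",
         call. = FALSE)
  }
  structure(
    list(
      values = values,
      variable_names = variable_names,
      group_labels = group_labels,
      group_sizes = stats::setNames(as.integer(sizes), levels(group_labels)),
      n_dropped = as.integer(n_dropped)
    ),
    class = "grouped_dataset"
  )
}

#' Read a delimited samples x variables table with a group column
#'
#' Loads a concentration table (one header row, samples in rows), pulls the
#' group column out, coerces the remaining columns to numeric and drops rows
#' with any missing value (complete-case analysis; the count of dropped rows
#' is retained in the result and reported).
#'
#' @param path Path to a delimited text file.
#' @param group_column Name of the column holding the two-level group label.
#' @param delimiter Field delimiter (default tab).
#' @return A [grouped_dataset()].
#' @export
read_grouped_table <- function(path, group_column, delimiter = "\t") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"")
  if (!group_column %in% names(raw)) {
    stop("group column '", group_column, "' not found in ", path, call. = FALSE)
  }
  labels_raw <- as.character(raw[[group_column]])
  vars <- raw[setdiff(names(raw), group_column)]
  for (nm in names(vars)) {
    if (!is.numeric(vars[[nm]])) {
      coerced <- suppressWarnings(as.numeric(vars[[nm]]))
      introduced <- is.na(coerced) & !is.na(vars[[nm]]) &
        !(trimws(as.character(vars[[nm]])) %in% c("NA", ""))
      if (any(introduced)) {
        stop("non-numeric values in variable column '", nm, "'", call. = FALSE)
      }
      vars[[nm]] <- coerced
    }
  }
  values <- as.matrix(vars)
  keep <- stats::complete.cases(values) & !is.na(labels_raw)
  n_dropped <- sum(!keep)
  values <- values[keep, , drop = FALSE]
  labels_raw <- labels_raw[keep]
  lv <- unique(labels_raw)
  if (length(lv) != 2L) {
    stop("expected exactly two groups in column '", group_column,
         "', found ", length(lv), ": ", paste(lv, collapse = ", "),
         call. = FALSE)
  }
  ds <- grouped_dataset(values, factor(labels_raw, levels = lv),
                        n_dropped = n_dropped)
  if (n_dropped > 0) {
    message("dropped ", n_dropped, " row(s) with missing values")
  }
  ds
}

#' @export
print.grouped_dataset <- function(x, ...) {
  cat("Two-group dataset:", nrow(x$values), "samples x",
      ncol(x$values), "variables\n")
  cat("  groups: ", paste(names(x$group_sizes), x$group_sizes,
                          sep = " n=", collapse = ", "), "\n", sep = "")
  if (x$n_dropped > 0) {
    cat("  rows dropped for missingness:", x$n_dropped, "\n")
  }
  invisible(x)
}

# Rows of one group as a plain matrix.
group_values <- function(data, group) {
  stopifnot(inherits(data, "grouped_dataset"))
  group <- as.character(group)
  if (!group %in% levels(data$group_labels)) {
    stop("unknown group '", group, "'; available: ",
         paste(levels(data$group_labels), collapse = ", "), call. = FALSE)
  }
  data$values[data$group_labels == group, , drop = FALSE]
}
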