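#' Construct a cell table
#'
#' A cell table is the central data structure of annotlink: one record per
#' cell (or other data point), a unique string `cell_id` per record, and any
#' number of annotation columns, each tagged either `"categorical"` (string
#' values) or `"numeric"` (finite real values). Missing values (`NA`) are
#' allowed in both kinds and are excluded from all counts unless an
#' operation states otherwise.
#'
#' @param data A data frame of annotation columns. If it contains a column
#'   named `cell_id` that column is used as the identifier; otherwise
#'   `cell_id` must be supplied (or row names are used as a fallback).
#' @param cell_id Optional character vector of unique, non-empty identifiers,
#'   one per row of `data`.
#' @param kinds Optional named character vector overriding the inferred kind
#'   (`"categorical"` or `"numeric"`) for specific columns. By default a
#'   column is numeric iff every non-missing entry is a finite real (or
#'   parses as one), otherwise categorical.
#'
#' @return An object of class `cell_table` with fields `cell_id` (character),
#'   `data` (tibble of annotation columns; categorical columns are character,
#'   numeric columns double) and `kinds` (named character vector).
#' @examples
#' ct <- cell_table(data.frame(
#'   cell_id = c("c1", "c2", "c3"),
#'   class = c("Endo", "Micro", "Endo"),
#'   n_genes = c(2100, 950, 3300)
#' ))
#' n_cells(ct)
#' column_kinds(ct)
#' @export
cell_table <- function(data, cell_id = NULL, kinds = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(cell_id)) {
    if ("cell_id" %in% names(data)) {
      cell_id <- as.character(data[["cell_id"]])
      data[["cell_id"]] <- NULL
    } else if (tibble::has_rownames(data)) {
      cell_id <- rownames(data)
    } else {
      stop("`data` has no `cell_id` column and no `cell_id` was supplied",
           call. = FALSE)
    }
  }
  cell_id <- as.character(cell_id)
  if (length(cell_id) != nrow(data)) {
    stop("`cell_id` length (", length(cell_id), ") does not match row count (",
         nrow(data), ")", call. = FALSE)
  }
  if (anyNA(cell_id) || any(!nzchar(cell_id))) {
    stop("`cell_id` values must be non-empty and non-missing", call. = FALSE)
  }
  dup <- unique(cell_id[duplicated(cell_id)])
  if (length(dup) > 0) {
    stop("duplicate cell_id value(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }

  inferred <- vapply(data, infer_kind, character(1))
  if (!is.null(kinds)) {
    bad <- setdiff(names(kinds), names(data))
    if (length(bad) > 0) {
      stop("kind override for absent column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    stopifnot(all(kinds %in% c("categorical", "numeric")))
    inferred[names(kinds)] <- kinds
  }
  for (nm in names(data)) {
    data[[nm]] <- if (inferred[[nm]] == "numeric") {
      coerce_numeric_column(data[[nm]], nm)
    } else {
      as.character(data[[nm]])
    }
  }
  structure(
    list(cell_id = cell_id, data = data, kinds = inferred),
    class = "cell_table"
  )
}

# numeric iff every non-missing entry is (or parses as) a finite real
infer_kind <- function(x) {
  if (is.numeric(x)) {
    if (all(is.finite(x) | is.na(x))) "numeric" else "categorical"
  } else if (is.logical(x)) {
    "categorical"
  } else {
    x <- as.character(x)
    x <- x[!is.na(x)]
    if (length(x) == 0) return("categorical")
    parsed <- suppressWarnings(as.numeric(x))
    if (all(is.finite(parsed))) "numeric" else "categorical"
  }
}

coerce_numeric_column <- function(x, nm) {
  out <- suppressWarnings(as.numeric(as.character(x)))
  if (any(is.na(out) & !is.na(x))) {
    stop("column `", nm, "` is tagged numeric but has unparseable entries",
         call. = FALSE)
  }
  out
}

#' @rdname cell_table
#' @param x A `cell_table`.
#' @export
n_cells <- function(x) {
  stopifnot(is_cell_table(x))
  length(x$cell_id)
}

#' @rdname cell_table
#' @export
column_kinds <- function(x) {
  stopifnot(is_cell_table(x))
  x$kinds
}

#' @rdname cell_table
#' @export
is_cell_table <- function(x) inherits(x, "cell_table")

#' Convert a cell table to a tibble
#'
#' Returns the annotation columns with `cell_id` restored as the first
#' column, suitable for writing or for dplyr-style manipulation.
#'
#' @param x A `cell_table`.
#' @param ... Unused.
#' @exportS3Method tibble::as_tibble
#' @export
as_tibble.cell_table <- function(x, ...) {
  tibble::add_column(x$data, cell_id = x$cell_id, .before = 1)
}

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> ", n_cells(x), " cells x ", ncol(x$data),
      " annotation columns\n", sep = "")
  if (ncol(x$data) > 0) {
    cat(paste0("  ", names(x$kinds), " <", x$kinds, ">", collapse = "\n"),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
`==.cell_table` <- function(e1, e2) {
  isTRUE(all.equal(e1$cell_id, e2$cell_id)) &&
    isTRUE(all.equal(e1$kinds, e2$kinds)) &&
    isTRUE(all.equal(as.data.frame(e1$data), as.data.frame(e2$data)))
}

# Subset records of a cell table by a logical/integer index, keeping order.
subset_cells <- function(x, idx) {
  structure(
    list(cell_id = x$cell_id[idx], data = x$data[idx, , drop = FALSE],
         kinds = x$kinds),
    class = "cell_table"
  )
}

check_column <- function(table, col, kind = NULL) {
  if (!col %in% names(table$data)) {
    stop("column `", col, "` not found in cell table", call. = FALSE)
  }
  if (!is.null(kind) && table$kinds[[col]] != kind) {
    stop("column `", col, "` is ", table$kinds[[col]], ", expected ", kind,
         call. = FALSE)
  }
  invisible(TRUE)
}
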