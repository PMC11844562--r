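#' Load a cell table from file
#'
#' Reads one record per cell from csv, gzip-compressed csv, feather (Arrow
#' IPC file) or h5ad. For h5ad only the per-cell metadata table (`obs`) is
#' read, with the obs index as `cell_id`; the expression matrix is ignored.
#' For tabular formats the identifier is the `cell_id` column when present,
#' otherwise the file's row index (as `"1"`, `"2"`, ...).
#'
#' Column kinds are inferred: a column is numeric iff every non-missing
#' entry parses as a finite real, otherwise categorical. Integer-coded
#' categories can be forced categorical via `kinds` or a config file (see
#' [read_annotlink_config()]). In csv input the empty string and the
#' literal `NA` are read as missing.
#'
#' @param path Path to the input file.
#' @param format_hint Optional format override, one of `"csv"`, `"csv_gz"`,
#'   `"feather"`, `"h5ad"`. By default the format is inferred from the file
#'   extension.
#' @param kinds Optional named character vector of per-column kind
#'   overrides (`"categorical"` / `"numeric"`).
#' @param missing_tokens Extra strings treated as missing in csv input, in
#'   addition to the empty string and `NA`.
#' @return A [cell_table()] whose records equal the file's rows, in file
#'   order.
#' @export
load_cell_table <- function(path, format_hint = NULL, kinds = NULL,
                            missing_tokens = character()) {
  if (!file.exists(path)) {
    stop("cannot read cell table: no such file: ", path, call. = FALSE)
  }
  fmt <- format_hint %||% infer_format(path)
  fmt <- match.arg(fmt, c("csv", "csv_gz", "feather", "h5ad"))
  df <- switch(fmt,
    csv = ,
    csv_gz = readr::read_csv(path, col_types = readr::cols(.default = "c"),
                             na = c("", "NA", missing_tokens),
                             progress = FALSE, show_col_types = FALSE),
    feather = tibble::as_tibble(arrow::read_feather(path)),
    h5ad = read_h5ad_obs(path)
  )
  id <- if ("cell_id" %in% names(df)) {
    out <- as.character(df[["cell_id"]])
    df[["cell_id"]] <- NULL
    out
  } else {
    as.character(seq_len(nrow(df)))
  }
  cell_table(df, cell_id = id, kinds = kinds)
}

infer_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.csv\\.gz$", lower)) return("csv_gz")
  if (grepl("\\.csv$", lower)) return("csv")
  if (grepl("\\.feather$|\\.arrow$", lower)) return("feather")
  if (grepl("\\.h5ad$", lower)) return("h5ad")
  stop("cannot infer format from extension of ", path,
       "; pass `format_hint`", call. = FALSE)
}

# Read the per-cell metadata (obs) of an h5ad file as a tibble whose first
# column is cell_id (the obs index). Handles the anndata on-disk encodings
# for dataframes: categorical (codes + categories), nullable integer/boolean
# (values + mask), and plain arrays.
read_h5ad_obs <- function(path) {
  obs <- rhdf5::h5read(path, "obs", read.attributes = TRUE)
  attrs <- rhdf5::h5readAttributes(path, "obs")
  index_name <- as.character(attrs[["_index"]] %||% "_index")
  col_order <- as.character(attrs[["column-order"]] %||%
                              setdiff(names(obs), index_name))
  decode <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$categories) && !is.null(x$codes)) {
        codes <- as.integer(x$codes)
        out <- rep(NA_character_, length(codes))
        ok <- codes >= 0
        out[ok] <- as.character(x$categories)[codes[ok] + 1L]
        return(out)
      }
      if (!is.null(x$values) && !is.null(x$mask)) {
        vals <- x$values
        vals[as.logical(x$mask)] <- NA
        return(as.vector(vals))
      }
      stop("unsupported h5ad obs column encoding", call. = FALSE)
    }
    as.vector(x)
  }
  cols <- lapply(obs[col_order], decode)
  names(cols) <- col_order
  df <- tibble::as_tibble(cols)
  df <- tibble::add_column(df,
    cell_id = as.character(decode(obs[[index_name]])), .before = 1)
  df
}

#' Write a cell table to file
#'
#' The inverse of [load_cell_table()] for the writable formats:
#' `load_cell_table(write_cell_table(t, path), ...)` reproduces `t`
#' (values, column kinds and row order), provided categorical columns do
#' not consist solely of number-like strings (csv carries no type
#' metadata; use a kind override on reload in that case, or feather, which
#' preserves types natively). Missing values are written as empty fields
#' in csv.
#'
#' @param table A [cell_table()].
#' @param path Output path.
#' @param format One of `"csv"`, `"csv_gz"`, `"feather"`; inferred from the
#'   extension when omitted.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path, format = NULL) {
  stopifnot(is_cell_table(table))
  fmt <- format %||% infer_format(path)
  fmt <- match.arg(fmt, c("csv", "csv_gz", "feather"))
  df <- as_tibble.cell_table(table)
  switch(fmt,
    csv = ,
    csv_gz = readr::write_csv(df, path, na = "", progress = FALSE),
    feather = arrow::write_feather(df, path)
  )
  invisible(path)
}

#' Validate a cell table against its annotation info
#'
#' Collects structural problems instead of raising them: duplicate cell
#' identifiers and reserved-label misuse are errors; annotation-info
#' entries referencing columns absent from the table, or values absent
#' from their column, are warnings.
#'
#' @param table A [cell_table()].
#' @param info Optional [annotation_info()].
#' @return A `validation_report`: list with `errors` (tibble of severity,
#'   location, message) and `is_valid` (`TRUE` iff no error-severity
#'   entries exist).
#' @export
validate_cells <- function(table, info = NULL) {
  stopifnot(is_cell_table(table))
  sev <- character(); loc <- character(); msg <- character()
  note <- function(severity, location, message) {
    sev <<- c(sev, severity); loc <<- c(loc, location)
    msg <<- c(msg, message)
  }

  dup <- unique(table$cell_id[duplicated(table$cell_id)])
  for (d in dup) note("error", "cell_id", paste0("duplicate cell_id: ", d))

  for (nm in names(table$data)) {
    if (table$kinds[[nm]] == "categorical" &&
        any(table$data[[nm]] == "noMappedCells", na.rm = TRUE)) {
      note("warning", nm,
           "uses the reserved label \"noMappedCells\" as a category")
    }
  }

  if (!is.null(info)) {
    for (col in unique(info$column_name)) {
      if (!col %in% names(table$data)) {
        note("warning", col,
             "annotation info references a column absent from the table")
        next
      }
      seen <- unique(table$data[[col]])
      absent <- setdiff(info$value[info$column_name == col], seen)
      for (v in absent) {
        note("warning", col,
             paste0("annotation info value \"", v,
                    "\" does not occur in the table"))
      }
    }
  }

  errors <- tibble::tibble(severity = sev, location = loc, message = msg)
  structure(list(errors = errors, is_valid = !any(sev == "error")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ",
      if (x$is_valid) "valid" else "INVALID", "; ",
      nrow(x$errors), " finding(s)\n", sep = "")
  if (nrow(x$errors) > 0) {
    cat(paste0("  [", x$errors$severity, "] ", x$errors$location, ": ",
               x$errors$message, collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}

#' Read an annotlink config file
#'
#' A YAML file with optional keys `kinds` (a map from column name to
#' `"categorical"`/`"numeric"`, applied as overrides on load) and
#' `missing_tokens` (extra strings to treat as missing in csv input).
#'
#' @param path Path to the YAML config.
#' @return A list with elements `kinds` and `missing_tokens`.
#' @export
read_annotlink_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  kinds <- unlist(cfg$kinds %||% list())
  list(kinds = if (length(kinds)) kinds else NULL,
       missing_tokens = as.character(cfg$missing_tokens %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
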