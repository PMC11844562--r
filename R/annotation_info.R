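#' Construct an annotation-info table
#'
#' The annotation-info table carries per-(column, value) display metadata:
#' an integer display rank (`order`), a free-text `description` (aliases,
#' marker genes), the reported `direction` of abundance change with disease
#' (`up`, `down`, `unchanged`, or `unknown`), and free-text `notes`. The
#' order of values within a column dictates the order in which they are
#' shown in every visualization and statistic.
#'
#' @param df A data frame with at least columns `column_name` and `value`;
#'   optional columns `order`, `description`, `direction`, `notes`. When
#'   `order` is absent, file/row order within each `column_name` is used.
#'   Direction strings outside the fixed vocabulary are mapped to
#'   `"unknown"` with a warning.
#'
#' @return An object of class `annotation_info`: a tibble with columns
#'   `column_name`, `value`, `order`, `description`, `direction`, `notes`.
#' @examples
#' info <- annotation_info(data.frame(
#'   column_name = c("celltype", "celltype"),
#'   value = c("Sst_25", "Sst_1"),
#'   direction = c("down", "unchanged")
#' ))
#' direction_of(info, "celltype", c("Sst_1", "Sst_25", "Vip_3"))
#' @export
annotation_info <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("column_name", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("annotation info lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$column_name <- as.character(df$column_name)
  df$value <- as.character(df$value)
  key <- paste(df$column_name, df$value, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    stop("duplicate (column, value) pair(s): ",
         paste(gsub("\r", ", ", utils::head(dup, 5)), collapse = "; "),
         call. = FALSE)
  }
  if (!"order" %in% names(df)) {
    df$order <- stats::ave(seq_len(nrow(df)), df$column_name,
                           FUN = seq_along)
  }
  df$order <- as.integer(df$order)
  tied <- tapply(df$order, df$column_name, function(o) anyDuplicated(o) > 0)
  if (any(tied)) {
    stop("tied display order within column(s): ",
         paste(names(tied)[tied], collapse = ", "), call. = FALSE)
  }
  if (!"description" %in% names(df)) df$description <- NA_character_
  if (!"notes" %in% names(df)) df$notes <- NA_character_
  if (!"direction" %in% names(df)) {
    df$direction <- "unknown"
  } else {
    df$direction <- normalize_direction(as.character(df$direction))
  }
  df <- df[, c("column_name", "value", "order", "description", "direction",
               "notes")]
  structure(df, class = c("annotation_info", class(df)))
}

direction_levels <- c("up", "down", "unchanged", "unknown")

normalize_direction <- function(x) {
  x[is.na(x) | !nzchar(x)] <- "unknown"
  bad <- setdiff(unique(x), direction_levels)
  if (length(bad) > 0) {
    warning("unrecognized direction value(s) mapped to \"unknown\": ",
            paste(bad, collapse = ", "), call. = FALSE)
    x[x %in% bad] <- "unknown"
  }
  x
}

#' @rdname annotation_info
#' @param x An object.
#' @export
is_annotation_info <- function(x) inherits(x, "annotation_info")

#' Look up the direction tag of annotation values
#'
#' @param info An `annotation_info` (or `NULL`).
#' @param column Annotation column name.
#' @param values Character vector of values to look up.
#' @return Character vector of directions; `"unknown"` for any (column,
#'   value) pair not present in `info`.
#' @export
direction_of <- function(info, column, values) {
  out <- rep("unknown", length(values))
  if (is.null(info)) return(out)
  sub <- info[info$column_name == column, , drop = FALSE]
  hit <- match(values, sub$value)
  out[!is.na(hit)] <- sub$direction[hit[!is.na(hit)]]
  out
}

#' Display order of values for an annotation column
#'
#' Returns the labels `values` sorted by the info table's display rank.
#' Values not covered by `info` (or all values when `info` is `NULL`) fall
#' back to descending count order with lexicographic tie-breaking, after
#' any info-ordered values.
#'
#' @param info An `annotation_info` or `NULL`.
#' @param column Annotation column name.
#' @param values Character vector of observed labels.
#' @param counts Optional numeric vector of per-label counts (same length
#'   as `values`) used by the fallback rule; defaults to zero.
#' @return `values`, reordered.
#' @export
value_order <- function(info, column, values, counts = NULL) {
  if (is.null(counts)) counts <- rep(0, length(values))
  stopifnot(length(counts) == length(values))
  rank_info <- rep(NA_integer_, length(values))
  if (!is.null(info)) {
    sub <- info[info$column_name == column, , drop = FALSE]
    hit <- match(values, sub$value)
    rank_info[!is.na(hit)] <- sub$order[hit[!is.na(hit)]]
  }
  covered <- !is.na(rank_info)
  ordered_covered <- values[covered][order(rank_info[covered])]
  rest <- order(-counts[!covered], values[!covered])
  c(ordered_covered, values[!covered][rest])
}

#' Read an annotation-info table from csv
#'
#' Expects at least columns naming the annotation column and the value
#' (`column_name`/`value`; the aliases `annotation`/`name` are also
#' accepted). A `direction` column is optional; absent or unrecognized
#' directions become `"unknown"`. Display order is taken from file row
#' order within each annotation column.
#'
#' @param path Path to a csv (or csv.gz) file.
#' @return An `annotation_info`.
#' @export
load_annotation_info <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read annotation info: no such file: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        na = c("", "NA"), progress = FALSE,
                        show_col_types = FALSE)
  nm <- names(df)
  if (!"column_name" %in% nm && "annotation" %in% nm) {
    names(df)[nm == "annotation"] <- "column_name"
  }
  if (!"value" %in% names(df) && "name" %in% names(df)) {
    names(df)[names(df) == "name"] <- "value"
  }
  df$order <- NULL  # order is defined by file row order
  annotation_info(df)
}
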