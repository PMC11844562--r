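#' Cross-tabulate two categorical annotations
#'
#' Builds the confusion matrix between two categorical columns over the
#' records non-missing in BOTH columns: entry (i, j) counts the records
#' with value i in `col_a` and value j in `col_b`. Labels are ordered by
#' the annotation-info display rank when `info` covers the column, else by
#' descending count with lexicographic tie-breaking.
#'
#' @param table A [cell_table()].
#' @param col_a,col_b Names of categorical columns.
#' @param info Optional [annotation_info()] controlling label order.
#' @return A `confusion_matrix`: an integer matrix with `dimnames`
#'   (values of `col_a` as rows, `col_b` as columns) and attributes
#'   `col_a`, `col_b`.
#' @examples
#' ct <- make_toy_neurons()
#' cm <- crosstab(ct, "size_v1", "size_v2")
#' sum(cm)  # 8 neurons carry both size annotations
#' @export
crosstab <- function(table, col_a, col_b, info = NULL) {
  stopifnot(is_cell_table(table))
  check_column(table, col_a, "categorical")
  check_column(table, col_b, "categorical")
  a <- table$data[[col_a]]
  b <- table$data[[col_b]]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  rows <- ordered_labels(table, col_a, info)
  cols <- ordered_labels(table, col_b, info)
  m <- table(factor(a, levels = rows), factor(b, levels = cols))
  m <- matrix(as.integer(m), nrow = length(rows),
              dimnames = list(rows, cols))
  structure(m, col_a = col_a, col_b = col_b,
            class = c("confusion_matrix", "matrix", "array"))
}

# All labels observed in a column, display-ordered.
ordered_labels <- function(table, col, info) {
  x <- table$data[[col]]
  tab <- table(x[!is.na(x)])
  value_order(info, col, names(tab), as.integer(tab))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> ", attr(x, "col_a"), " x ", attr(x, "col_b"),
      " (", sum(x), " cells)\n", sep = "")
  print(unclass_cm(x))
  invisible(x)
}

unclass_cm <- function(x) {
  attr(x, "col_a") <- NULL
  attr(x, "col_b") <- NULL
  class(x) <- c("matrix", "array")
  x
}

#' Jaccard-similarity view of a confusion matrix
#'
#' For row label i and column label j with overlap n_ij, the Jaccard
#' similarity of the two record sets is
#' `J_ij = n_ij / (row_total_i + col_total_j - n_ij)` — intersection over
#' union. An empty union (both sets empty) yields `J = 0`.
#'
#' @param cm A [crosstab()] result.
#' @return A numeric matrix in `[0, 1]` with the same dimnames as `cm`.
#' @export
jaccard_view <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- unclass_cm(cm)
  union <- outer(rowSums(n), colSums(n), `+`) - n
  j <- ifelse(union > 0, n / union, 0)
  dimnames(j) <- dimnames(n)
  j
}

#' Fraction view of a confusion matrix
#'
#' Divides each entry by its row total (`axis = "row"`; every nonempty row
#' then sums to 1) or its column total. Rows or columns with total zero
#' are left all-zero.
#'
#' @param cm A [crosstab()] result.
#' @param axis `"row"` or `"column"`.
#' @return A numeric matrix in `[0, 1]`.
#' @export
fraction_view <- function(cm, axis = c("row", "column")) {
  stopifnot(inherits(cm, "confusion_matrix"))
  axis <- match.arg(axis)
  n <- unclass_cm(cm)
  totals <- if (axis == "row") rowSums(n) else colSums(n)
  safe <- ifelse(totals > 0, totals, 1)
  out <- if (axis == "row") n / safe else sweep(n, 2, safe, `/`)
  dimnames(out) <- dimnames(n)
  out
}

#' Build a river (alluvial) model over ordered annotation columns
#'
#' Arranges two or more categorical columns side by side; each column
#' contributes one node per category (node count = records non-missing in
#' that column) and each adjacent pair of columns contributes links whose
#' counts are the pairwise crosstab of the two columns. Links between a
#' given pair use the records non-missing in both of those columns
#' (pairwise-complete, not listwise across all columns), so count
#' conservation holds per adjacent pair.
#'
#' @param table A [cell_table()].
#' @param cols Ordered character vector of >= 2 categorical column names.
#' @param info Optional [annotation_info()] controlling node order.
#' @return A `river_model`: list with `columns`, `nodes` (tibble: column,
#'   value, count) and `links` (tibble: from_column, from_value,
#'   to_column, to_value, count; zero-count links omitted).
#' @export
river_model <- function(table, cols, info = NULL) {
  stopifnot(is_cell_table(table))
  if (length(cols) < 2) {
    stop("river model needs at least 2 columns", call. = FALSE)
  }
  for (col in cols) check_column(table, col, "categorical")

  nodes <- dplyr::bind_rows(lapply(cols, function(col) {
    labs <- ordered_labels(table, col, info)
    x <- table$data[[col]]
    tab <- table(factor(x[!is.na(x)], levels = labs))
    tibble::tibble(column = col, value = labs, count = as.integer(tab))
  }))

  links <- dplyr::bind_rows(lapply(seq_len(length(cols) - 1), function(k) {
    cm <- crosstab(table, cols[k], cols[k + 1], info)
    long <- as.data.frame.table(unclass_cm(cm), stringsAsFactors = FALSE)
    names(long) <- c("from_value", "to_value", "count")
    long <- long[long$count > 0, , drop = FALSE]
    tibble::tibble(from_column = cols[k], from_value = long$from_value,
                   to_column = cols[k + 1], to_value = long$to_value,
                   count = as.integer(long$count))
  }))

  structure(list(columns = cols, nodes = nodes, links = links),
            class = "river_model")
}

#' @export
print.river_model <- function(x, ...) {
  cat("<river_model> ", length(x$columns), " columns, ", nrow(x$nodes),
      " nodes, ", nrow(x$links), " links\n", sep = "")
  invisible(x)
}

#' Write a river model as JSON
#'
#' Serializes the model as a document `{columns, nodes, links}` with
#' stable key names, so downstream plotting or web tools can consume it.
#'
#' @param model A [river_model()].
#' @param path Output JSON path.
#' @export
write_river_model <- function(model, path) {
  stopifnot(inherits(model, "river_model"))
  jsonlite::write_json(
    list(columns = model$columns, nodes = model$nodes, links = model$links),
    path, dataframe = "rows", auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' Break down a single annotation value across other columns
#'
#' Restricts the table to records carrying `focal_value` in `focal_col`
#' and tabulates, per other column, how those records distribute over its
#' values; each listed value carries its direction-of-change tag from the
#' annotation info (`"unknown"` when absent). This is the model behind
#' single-value bar plots colored by disease direction.
#'
#' @param table A [cell_table()].
#' @param focal_col,focal_value The focal categorical column and value.
#' @param other_cols Character vector of categorical columns to break
#'   down over.
#' @param info Optional [annotation_info()].
#' @return A `breakdown`: list with `focal_column`, `focal_value`,
#'   `n_focal`, and `entries` (tibble: column, value, count, direction).
#'   A focal value absent from the column yields an empty breakdown with
#'   a warning.
#' @export
value_breakdown <- function(table, focal_col, focal_value, other_cols,
                            info = NULL) {
  stopifnot(is_cell_table(table))
  check_column(table, focal_col, "categorical")
  for (col in other_cols) check_column(table, col, "categorical")

  keep <- !is.na(table$data[[focal_col]]) &
    table$data[[focal_col]] == focal_value
  empty <- tibble::tibble(column = character(), value = character(),
                          count = integer(), direction = character())
  if (!any(keep)) {
    warning("focal value \"", focal_value, "\" does not occur in column `",
            focal_col, "`", call. = FALSE)
    return(structure(list(focal_column = focal_col,
                          focal_value = focal_value, n_focal = 0L,
                          entries = empty),
                     class = "breakdown"))
  }
  sub <- subset_cells(table, keep)
  entries <- dplyr::bind_rows(lapply(other_cols, function(col) {
    labs <- ordered_labels(table, col, info)
    x <- sub$data[[col]]
    tab <- table(factor(x[!is.na(x)], levels = labs))
    tab <- tab[tab > 0]
    if (length(tab) == 0) return(empty)
    tibble::tibble(column = col, value = names(tab),
                   count = as.integer(tab),
                   direction = direction_of(info, col, names(tab)))
  }))
  structure(list(focal_column = focal_col, focal_value = focal_value,
                 n_focal = n_cells(sub), entries = entries),
            class = "breakdown")
}

#' @export
print.breakdown <- function(x, ...) {
  cat("<breakdown> ", x$focal_column, " = \"", x$focal_value, "\" (",
      x$n_focal, " cells) across ",
      length(unique(x$entries$column)), " column(s)\n", sep = "")
  invisible(x)
}

#' Tally direction concordance across compared columns
#'
#' For each column a breakdown touches, tallies the direction tags of its
#' matched values — the values that co-occur with the focal value — and
#' reports the dominant direction. This is how "cell loss reported in k
#' of n studies" summaries are computed: each compared column plays the
#' role of one study.
#'
#' @param bd A [value_breakdown()] result.
#' @param info The [annotation_info()] carrying direction tags (already
#'   baked into `bd`; accepted for symmetry and re-tagging).
#' @param weighting `"by_value"` counts each matched value once;
#'   `"by_cell"` weights each value by its record count.
#' @return A `direction_tally` tibble: one row per compared column with
#'   counts of `up`/`down`/`unchanged`/`unknown` and the `dominant`
#'   direction (ties give `"unknown"`).
#' @export
direction_concordance <- function(bd, info = NULL,
                                  weighting = c("by_value", "by_cell")) {
  stopifnot(inherits(bd, "breakdown"))
  weighting <- match.arg(weighting)
  entries <- bd$entries
  if (!is.null(info) && nrow(entries) > 0) {
    entries$direction <- unlist(Map(function(col, val)
      direction_of(info, col, val), entries$column, entries$value),
      use.names = FALSE)
  }
  out <- lapply(unique(entries$column), function(col) {
    sub <- entries[entries$column == col, , drop = FALSE]
    w <- if (weighting == "by_value") rep(1L, nrow(sub)) else sub$count
    tall <- vapply(direction_levels, function(d)
      sum(w[sub$direction == d]), numeric(1))
    top <- max(tall)
    winners <- direction_levels[tall == top]
    dominant <- if (length(winners) == 1) winners else "unknown"
    tibble::tibble(column = col, dominant = dominant,
                   up = tall[["up"]], down = tall[["down"]],
                   unchanged = tall[["unchanged"]],
                   unknown = tall[["unknown"]])
  })
  out <- dplyr::bind_rows(out)
  structure(out, class = c("direction_tally", class(out)))
}

#' Write a confusion matrix (or a metric view of it) as labeled csv
#'
#' @param m A `confusion_matrix` or a metric matrix derived from one.
#' @param path Output csv path.
#' @export
write_confusion <- function(m, path) {
  df <- as.data.frame(if (inherits(m, "confusion_matrix")) unclass_cm(m)
                      else m)
  df <- tibble::add_column(df, label = rownames(m), .before = 1)
  readr::write_csv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}
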