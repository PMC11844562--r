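#' Filters over cell-table columns
#'
#' A categorical filter keeps records whose value lies in `included`
#' (optionally inverted); a numeric filter keeps records inside a closed
#' range. Records with a missing value in a filtered column fail that
#' filter in both invert states: membership cannot be asserted for a
#' missing value, and keeping this rule fixed makes reported counts
#' reproducible.
#'
#' @param column Column name the filter applies to.
#' @param included Non-empty character vector of values to keep.
#' @param invert If `TRUE`, keep records whose value is NOT in `included`.
#' @return A filter object usable in [filter_set()].
#' @examples
#' fs <- filter_set(
#'   categorical_filter("class", c("Endo", "Micro")),
#'   numeric_filter("n_genes", lower = 500, upper = 8000)
#' )
#' @export
categorical_filter <- function(column, included, invert = FALSE) {
  included <- as.character(included)
  if (length(included) == 0) {
    stop("`included` must be non-empty", call. = FALSE)
  }
  structure(list(column = column, included = unique(included),
                 invert = isTRUE(invert)),
            class = c("categorical_filter", "annot_filter"))
}

#' @rdname categorical_filter
#' @param lower,upper Inclusive range bounds; `-Inf` / `Inf` leave a side
#'   open.
#' @export
numeric_filter <- function(column, lower = -Inf, upper = Inf) {
  stopifnot(is.numeric(lower), is.numeric(upper))
  if (lower > upper) stop("`lower` must be <= `upper`", call. = FALSE)
  structure(list(column = column, lower = lower, upper = upper),
            class = c("numeric_filter", "annot_filter"))
}

#' @rdname categorical_filter
#' @param ... Filters, at most one per column.
#' @export
filter_set <- function(...) {
  filters <- list(...)
  if (length(filters) == 1 && is.list(filters[[1]]) &&
      !inherits(filters[[1]], "annot_filter")) {
    filters <- filters[[1]]
  }
  stopifnot(all(vapply(filters, inherits, logical(1), "annot_filter")))
  cols <- vapply(filters, `[[`, character(1), "column")
  if (anyDuplicated(cols)) {
    stop("at most one filter per column; duplicated: ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "),
         call. = FALSE)
  }
  structure(filters, class = "filter_set")
}

filter_mask <- function(table, f) {
  if (inherits(f, "categorical_filter")) {
    check_column(table, f$column, "categorical")
    x <- table$data[[f$column]]
    hit <- x %in% f$included
    if (f$invert) hit <- !hit
    hit & !is.na(x)
  } else {
    check_column(table, f$column, "numeric")
    x <- table$data[[f$column]]
    !is.na(x) & x >= f$lower & x <= f$upper
  }
}

#' Restrict a cell table to records passing every filter
#'
#' Filters compose conjunctively: a record is retained iff it satisfies
#' ALL filters in the set. Row order is preserved. An empty filter set
#' returns the table unchanged.
#'
#' @param table A [cell_table()].
#' @param filters A [filter_set()].
#' @return A [cell_table()] of the retained records.
#' @export
apply_filter_set <- function(table, filters) {
  stopifnot(is_cell_table(table), inherits(filters, "filter_set"))
  if (length(filters) == 0) return(table)
  keep <- rep(TRUE, n_cells(table))
  for (f in filters) keep <- keep & filter_mask(table, f)
  subset_cells(table, keep)
}

#' Summarize a selection
#'
#' Reports how many records the filter set retains out of the total, and
#' the per-value counts of every categorical column after filtering.
#'
#' @inheritParams apply_filter_set
#' @return A list with `n_retained`, `n_total`, and `value_counts`, a
#'   tibble (column, value, count) over the retained records.
#' @export
selection_summary <- function(table, filters = filter_set()) {
  kept <- apply_filter_set(table, filters)
  cat_cols <- names(kept$kinds)[kept$kinds == "categorical"]
  counts <- lapply(cat_cols, function(nm) {
    x <- kept$data[[nm]]
    tab <- table(x[!is.na(x)])
    tibble::tibble(column = nm, value = names(tab),
                   count = as.integer(tab))
  })
  structure(
    list(n_retained = n_cells(kept), n_total = n_cells(table),
         value_counts = dplyr::bind_rows(counts)),
    class = "selection_summary"
  )
}

#' @export
print.selection_summary <- function(x, ...) {
  cat("<selection_summary> retained ", x$n_retained, " of ", x$n_total,
      " cells\n", sep = "")
  invisible(x)
}

#' Serialize / deserialize a filter set
#'
#' Filter sets round-trip through YAML so a selection can be recorded next
#' to its outputs and replayed exactly.
#'
#' @param filters A [filter_set()].
#' @param path Destination (or source) YAML path.
#' @return `write_filter_set` returns `path` invisibly; `read_filter_set`
#'   returns a [filter_set()].
#' @export
write_filter_set <- function(filters, path) {
  stopifnot(inherits(filters, "filter_set"))
  spec <- lapply(filters, function(f) {
    if (inherits(f, "categorical_filter")) {
      list(type = "categorical", column = f$column,
           included = as.list(f$included), invert = f$invert)
    } else {
      list(type = "numeric", column = f$column,
           lower = unbounded_to_chr(f$lower),
           upper = unbounded_to_chr(f$upper))
    }
  })
  yaml::write_yaml(list(filters = spec), path)
  invisible(path)
}

#' @rdname write_filter_set
#' @export
read_filter_set <- function(path) {
  spec <- yaml::read_yaml(path)$filters
  filter_set(lapply(spec, function(f) {
    if (identical(f$type, "categorical")) {
      categorical_filter(f$column, unlist(f$included),
                         invert = isTRUE(f$invert))
    } else {
      numeric_filter(f$column, chr_to_unbounded(f$lower, -Inf),
                     chr_to_unbounded(f$upper, Inf))
    }
  }))
}

unbounded_to_chr <- function(x) if (is.finite(x)) x else as.character(x)
chr_to_unbounded <- function(x, default) {
  if (is.null(x)) default else as.numeric(x)
}
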