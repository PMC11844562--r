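#' Plot style options
#'
#' Shared styling for all renderers. Dot sizes in confusion plots scale
#' linearly between `size_range[1]` (value 0) and `size_range[2]` (the
#' metric's maximum). Direction colors default to four fixed, distinct
#' colors: up = firebrick, down = steelblue, unchanged = grey60,
#' unknown = grey85.
#'
#' @param metric Metric for confusion plots: `"count"`, `"row_fraction"`,
#'   `"column_fraction"` or `"jaccard"`.
#' @param direction_colors Named character vector of colors for
#'   `up`/`down`/`unchanged`/`unknown`; must be distinct.
#' @param size_range Numeric length-2: dot size (mm) at zero and at the
#'   metric maximum.
#' @param width,height Figure dimensions in inches.
#' @param seed Integer seed for deterministic bee-swarm jitter.
#' @return A `plot_style` list.
#' @export
plot_style <- function(metric = c("count", "row_fraction",
                                  "column_fraction", "jaccard"),
                       direction_colors = c(up = "firebrick",
                                            down = "steelblue",
                                            unchanged = "grey60",
                                            unknown = "grey85"),
                       size_range = c(0.5, 8),
                       width = 7, height = 5, seed = 42L) {
  metric <- match.arg(metric)
  stopifnot(all(direction_levels %in% names(direction_colors)))
  if (anyDuplicated(direction_colors[direction_levels])) {
    stop("direction colors must be distinct", call. = FALSE)
  }
  structure(list(metric = metric, direction_colors = direction_colors,
                 size_range = size_range, width = width, height = height,
                 seed = as.integer(seed)),
            class = "plot_style")
}

save_plot <- function(p, path, style) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "svg", "pdf")) {
    stop("unsupported image format: .", ext, " (use png, svg or pdf)",
         call. = FALSE)
  }
  ggplot2::ggsave(path, p, width = style$width, height = style$height,
                  dpi = 150, bg = "white")
  invisible(path)
}

write_plot_data <- function(data, data_path) {
  if (is.null(data_path)) return(invisible(NULL))
  if (grepl("\\.json$", data_path)) {
    jsonlite::write_json(data, data_path, dataframe = "rows", digits = NA)
  } else {
    readr::write_csv(data, data_path, progress = FALSE)
  }
  invisible(data_path)
}

#' Render a river (alluvial) plot
#'
#' Draws the model's columns side by side; node bars are stacked in model
#' order and ribbons between adjacent columns have widths proportional to
#' their link counts. The computed layout (node and ribbon positions) can
#' be emitted as a sidecar file so encodings are testable without pixel
#' comparison.
#'
#' @param model A [river_model()].
#' @param style A [plot_style()].
#' @param path Output image path (`.png`, `.svg` or `.pdf`).
#' @param data_path Optional sidecar path (`.csv` or `.json`) for the
#'   plot-ready layout numbers.
#' @return Invisibly, a list with the node and link layout tibbles.
#' @export
render_river <- function(model, style = plot_style(), path,
                         data_path = NULL) {
  stopifnot(inherits(model, "river_model"))
  layout <- river_layout(model)

  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = layout$nodes,
      ggplot2::aes(xmin = .data$x - 0.12, xmax = .data$x + 0.12,
                   ymin = .data$ymin, ymax = .data$ymax,
                   fill = .data$value),
      color = "grey30", linewidth = 0.2, show.legend = FALSE
    ) +
    ggplot2::geom_text(
      data = layout$nodes,
      ggplot2::aes(x = .data$x, y = (.data$ymin + .data$ymax) / 2,
                   label = .data$value), size = 2.8
    ) +
    ggplot2::scale_x_continuous(breaks = seq_along(model$columns),
                                labels = model$columns,
                                limits = c(0.5, length(model$columns) + 0.5)) +
    ggplot2::labs(x = NULL, y = "cells") +
    ggplot2::theme_minimal()

  if (nrow(layout$links) > 0) {
    ribbons <- do.call(rbind, lapply(seq_len(nrow(layout$links)),
                                     function(i) {
      l <- layout$links[i, ]
      data.frame(
        ribbon = i,
        x = c(l$x_from + 0.12, l$x_to - 0.12, l$x_to - 0.12,
              l$x_from + 0.12),
        y = c(l$y_from_min, l$y_to_min, l$y_to_max, l$y_from_max)
      )
    }))
    p <- p + ggplot2::geom_polygon(
      data = ribbons,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$ribbon),
      fill = "grey55", alpha = 0.5
    )
  }

  save_plot(p, path, style)
  data <- dplyr::bind_rows(
    dplyr::mutate(layout$nodes, element = "node"),
    dplyr::mutate(layout$links, element = "link")
  )
  write_plot_data(data, data_path)
  invisible(layout)
}

# Stack nodes per column (model order, small gaps) and slot each link
# along its source and target nodes so ribbon widths equal link counts.
river_layout <- function(model) {
  gap <- max(1, round(0.02 * max(model$nodes$count, 1)))
  nodes <- dplyr::bind_rows(lapply(seq_along(model$columns), function(k) {
    sub <- model$nodes[model$nodes$column == model$columns[k], ]
    top <- cumsum(sub$count + gap)
    tibble::tibble(column = sub$column, value = sub$value,
                   count = sub$count, x = k,
                   ymin = top - sub$count - gap, ymax = top - gap)
  }))

  links <- model$links
  if (nrow(links) > 0) {
    key <- function(col, val) paste(col, val, sep = "\r")
    nkey <- key(nodes$column, nodes$value)
    links$x_from <- nodes$x[match(key(links$from_column, links$from_value),
                                  nkey)]
    links$x_to <- nodes$x[match(key(links$to_column, links$to_value), nkey)]
    base_from <- nodes$ymin[match(key(links$from_column, links$from_value),
                                  nkey)]
    base_to <- nodes$ymin[match(key(links$to_column, links$to_value), nkey)]
    off_from <- stats::ave(links$count, key(links$from_column,
                                            links$from_value),
                           FUN = function(v) cumsum(v) - v)
    off_to <- stats::ave(links$count, key(links$to_column, links$to_value),
                         FUN = function(v) cumsum(v) - v)
    links$y_from_min <- base_from + off_from
    links$y_from_max <- links$y_from_min + links$count
    links$y_to_min <- base_to + off_to
    links$y_to_max <- links$y_to_min + links$count
  }
  list(nodes = nodes, links = links)
}

#' Render a confusion-matrix dot plot
#'
#' Dot size and color encode the chosen metric (cell counts, row or
#' column fractions, or Jaccard similarity); axis label order follows the
#' matrix order. Sizes scale linearly between the style's `size_range`.
#'
#' @param cm A [crosstab()] result.
#' @inheritParams render_river
#' @return Invisibly, the plot-data tibble (row, col, count, value,
#'   size).
#' @export
render_confusion <- function(cm, style = plot_style(), path,
                             data_path = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  vals <- switch(style$metric,
    count = unclass_cm(cm),
    row_fraction = fraction_view(cm, "row"),
    column_fraction = fraction_view(cm, "column"),
    jaccard = jaccard_view(cm)
  )
  long <- as.data.frame.table(unclass_cm(cm), stringsAsFactors = FALSE)
  names(long) <- c("row", "col", "count")
  long$value <- as.vector(vals)
  vmax <- max(long$value, 0)
  long$size <- style$size_range[1] +
    (style$size_range[2] - style$size_range[1]) *
    (if (vmax > 0) long$value / vmax else 0)
  long <- tibble::as_tibble(long)

  shown <- long[long$count > 0, , drop = FALSE]
  p <- ggplot2::ggplot(shown,
    ggplot2::aes(x = factor(.data$col, levels = colnames(cm)),
                 y = factor(.data$row, levels = rev(rownames(cm))),
                 color = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$size)) +
    ggplot2::scale_size_identity() +
    ggplot2::scale_color_viridis_c(limits = c(0, max(vmax, 1e-12))) +
    ggplot2::labs(x = attr(cm, "col_b"), y = attr(cm, "col_a"),
                  color = style$metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  save_plot(p, path, style)
  write_plot_data(long, data_path)
  invisible(long)
}

#' Render a bee-swarm plot
#'
#' One swarm of points per value of `group_col`, showing the distribution
#' of a numeric annotation; points are colored by a second categorical
#' annotation and jittered horizontally with a deterministic seed so
#' repeated renders are identical.
#'
#' @param table A [cell_table()].
#' @param numeric_col Numeric column plotted on the y axis.
#' @param group_col Categorical column defining the swarms.
#' @param color_col Optional categorical column for point colors.
#' @param info Optional [annotation_info()] controlling group and legend
#'   order.
#' @inheritParams render_river
#' @return Invisibly, the plot-data tibble (group, x, y, color).
#' @export
render_beeswarm <- function(table, numeric_col, group_col,
                            color_col = NULL, info = NULL,
                            style = plot_style(), path, data_path = NULL) {
  stopifnot(is_cell_table(table))
  check_column(table, numeric_col, "numeric")
  check_column(table, group_col, "categorical")
  if (!is.null(color_col)) check_column(table, color_col, "categorical")

  g <- table$data[[group_col]]
  y <- table$data[[numeric_col]]
  keep <- !is.na(g) & !is.na(y)
  groups <- ordered_labels(table, group_col, info)
  gi <- match(g[keep], groups)
  jitter <- withr::with_seed(style$seed,
                             stats::runif(sum(keep), -0.3, 0.3))
  data <- tibble::tibble(
    group = g[keep], x = gi + jitter, y = y[keep],
    color = if (is.null(color_col)) NA_character_
            else table$data[[color_col]][keep]
  )

  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$x, y = .data$y)) +
    (if (is.null(color_col)) ggplot2::geom_point(alpha = 0.6, size = 0.8)
     else ggplot2::geom_point(ggplot2::aes(color = .data$color),
                              alpha = 0.6, size = 0.8)) +
    ggplot2::scale_x_continuous(breaks = seq_along(groups),
                                labels = groups,
                                limits = c(0.5, length(groups) + 0.5)) +
    ggplot2::labs(x = group_col, y = numeric_col, color = color_col) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  save_plot(p, path, style)
  write_plot_data(data, data_path)
  invisible(data)
}

#' Render a scatter plot of two numeric annotations
#'
#' One point per record with both coordinates non-missing — embedding
#' coordinates, spatial positions, electrophysiological parameters —
#' optionally colored by a categorical or numeric annotation; categorical
#' legends follow the annotation-info order.
#'
#' @param table A [cell_table()].
#' @param x_col,y_col Numeric coordinate columns.
#' @param color_col Optional column (either kind) for point colors.
#' @param info Optional [annotation_info()] controlling legend order.
#' @inheritParams render_river
#' @return Invisibly, the plot-data tibble (x, y, color).
#' @export
render_scatter <- function(table, x_col, y_col, color_col = NULL,
                           info = NULL, style = plot_style(), path,
                           data_path = NULL) {
  stopifnot(is_cell_table(table))
  check_column(table, x_col, "numeric")
  check_column(table, y_col, "numeric")
  if (!is.null(color_col)) check_column(table, color_col)

  x <- table$data[[x_col]]
  y <- table$data[[y_col]]
  keep <- !is.na(x) & !is.na(y)
  if (!any(keep)) {
    warning("no records with both `", x_col, "` and `", y_col,
            "` non-missing; rendering an empty plot", call. = FALSE)
  }
  data <- tibble::tibble(
    x = x[keep], y = y[keep],
    color = if (is.null(color_col)) NA else table$data[[color_col]][keep]
  )

  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = x_col, y = y_col, color = color_col) +
    ggplot2::theme_minimal()
  if (is.null(color_col)) {
    p <- p + ggplot2::geom_point(alpha = 0.6, size = 0.8)
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$color),
                                 alpha = 0.6, size = 0.8)
    if (table$kinds[[color_col]] == "categorical") {
      levels <- ordered_labels(table, color_col, info)
      p <- p + ggplot2::scale_color_discrete(limits = levels)
    }
  }
  save_plot(p, path, style)
  write_plot_data(data, data_path)
  invisible(data)
}
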