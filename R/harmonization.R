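#' Reserved label for reference cell types with no study counterpart
#' @export
NO_MAPPED_CELLS <- "noMappedCells"

#' Build a conditional proportion table linking two label columns
#'
#' Over the records where BOTH columns are non-missing, computes for each
#' reference label s the fraction of its cells carrying each study label
#' c: `p(c | s) = n_sc / n_s`. Reference labels that occur in the table's
#' reference column but are never co-observed with a study label receive
#' the reserved label `"noMappedCells"` with probability 1 — the situation
#' that arises when, say, neuronal supertypes are compared against a study
#' that annotated only glia.
#'
#' @param table A [cell_table()] carrying both columns (typically the
#'   shared-cell pairing of two studies).
#' @param ref_col Reference label column (e.g., mapped supertypes).
#' @param study_col The study's own label column.
#' @return A `proportion_table`: tibble (ref_label, study_label,
#'   probability) where probabilities sum to 1 within each ref_label.
#' @examples
#' pairing <- cell_table(data.frame(
#'   cell_id = paste0("c", 1:4),
#'   supertype = c("Sst_25", "Sst_25", "Sst_25", "Sst_25"),
#'   celltype = c("SST", "SST", "IN-a", "IN-b")
#' ))
#' proportion_table(pairing, "supertype", "celltype")
#' @export
proportion_table <- function(table, ref_col, study_col) {
  stopifnot(is_cell_table(table))
  check_column(table, ref_col, "categorical")
  check_column(table, study_col, "categorical")
  s <- table$data[[ref_col]]
  c_ <- table$data[[study_col]]
  keep <- !is.na(s) & !is.na(c_)
  if (!any(keep)) {
    stop("no records with both `", ref_col, "` and `", study_col,
         "` assigned", call. = FALSE)
  }
  tab <- table(s[keep], c_[keep])
  frac <- tab / rowSums(tab)
  long <- as.data.frame.table(frac, stringsAsFactors = FALSE)
  names(long) <- c("ref_label", "study_label", "probability")
  long <- long[long$probability > 0, , drop = FALSE]

  unmatched <- setdiff(unique(s[!is.na(s)]), rownames(tab))
  if (length(unmatched) > 0) {
    long <- rbind(long, data.frame(ref_label = unmatched,
                                   study_label = NO_MAPPED_CELLS,
                                   probability = 1))
  }
  long <- long[order(long$ref_label, -long$probability, long$study_label), ]
  new_proportion_table(tibble::as_tibble(long))
}

new_proportion_table <- function(df) {
  stopifnot(all(c("ref_label", "study_label", "probability") %in% names(df)))
  sums <- tapply(df$probability, df$ref_label, sum)
  if (any(abs(sums - 1) > 1e-12) || any(df$probability < 0) ||
      any(df$probability > 1)) {
    stop("proportion table probabilities must lie in [0,1] and sum to 1 ",
         "per reference label", call. = FALSE)
  }
  structure(df, class = c("proportion_table", class(df)))
}

#' Read / write a proportion table as long-format csv
#'
#' Columns: `ref_label`, `study_label`, `probability`.
#'
#' @param pt A `proportion_table`.
#' @param path csv path.
#' @export
write_proportion_table <- function(pt, path) {
  stopifnot(inherits(pt, "proportion_table"))
  readr::write_csv(tibble::as_tibble(unclass(pt)), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_proportion_table
#' @export
read_proportion_table <- function(path) {
  df <- readr::read_csv(path, col_types = "ccd", progress = FALSE,
                        show_col_types = FALSE)
  new_proportion_table(df)
}

#' Probabilistically assign study labels to reference cells
#'
#' Writes a new column in which every record with reference label s
#' receives an independent draw from the proportion table's distribution
#' p(. | s). Draws are consumed in table row order from a generator
#' seeded once per call, so identical (table, pt, seed) inputs give a
#' bit-identical assignment column. Records with a missing reference
#' label stay missing; reference labels present in the table but absent
#' from the proportion table are assigned `"noMappedCells"` with a
#' warning.
#'
#' @param table A [cell_table()].
#' @param pt A [proportion_table()].
#' @param ref_col Reference label column in `table`.
#' @param new_col Name of the column to create.
#' @param seed Integer seed.
#' @return `table` with `new_col` added (categorical); all existing
#'   columns untouched.
#' @export
probabilistic_assign <- function(table, pt, ref_col, new_col, seed) {
  stopifnot(is_cell_table(table), inherits(pt, "proportion_table"))
  check_column(table, ref_col, "categorical")
  if (new_col %in% names(table$data)) {
    stop("column `", new_col, "` already exists", call. = FALSE)
  }
  s <- table$data[[ref_col]]
  n <- length(s)
  dists <- split(pt[, c("study_label", "probability")], pt$ref_label)

  unknown <- setdiff(unique(s[!is.na(s)]), names(dists))
  if (length(unknown) > 0) {
    warning("reference label(s) absent from proportion table assigned \"",
            NO_MAPPED_CELLS, "\": ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }

  # one uniform per record, consumed in row order
  u <- withr::with_seed(seed, stats::runif(n))
  out <- rep(NA_character_, n)
  out[!is.na(s) & s %in% unknown] <- NO_MAPPED_CELLS
  for (lab in names(dists)) {
    idx <- which(!is.na(s) & s == lab)
    if (length(idx) == 0) next
    d <- dists[[lab]]
    cum <- cumsum(d$probability)
    cum[length(cum)] <- 1  # guard against rounding at the top end
    pick <- findInterval(u[idx], cum, left.open = TRUE) + 1L
    out[idx] <- d$study_label[pick]
  }

  table$data[[new_col]] <- out
  table$kinds[[new_col]] <- "categorical"
  table
}

#' Label hierarchy: fine label -> broad label
#'
#' @param mapping Named character vector: names are fine labels, values
#'   their broad labels. Total on the fine-label set it is applied to.
#' @return A `label_hierarchy`.
#' @export
label_hierarchy <- function(mapping) {
  stopifnot(is.character(mapping), !is.null(names(mapping)),
            all(nzchar(names(mapping))))
  if (anyDuplicated(names(mapping))) {
    stop("each fine label must map to exactly one broad label",
         call. = FALSE)
  }
  structure(mapping, class = "label_hierarchy")
}

#' Infer broad labels from fine labels
#'
#' Broader cell type definitions are inferred from their
#' higher-resolution counterparts: each fine label is replaced by its
#' broad label under the hierarchy. Missing stays missing and the
#' reserved `"noMappedCells"` label passes through verbatim.
#'
#' @param table A [cell_table()].
#' @param fine_col Categorical column of fine labels.
#' @param hierarchy A [label_hierarchy()] covering every non-missing fine
#'   value (else an error naming the misses).
#' @param new_col Name of the broad-label column to create.
#' @return `table` with `new_col` added.
#' @export
infer_broad_labels <- function(table, fine_col, hierarchy, new_col) {
  stopifnot(is_cell_table(table), inherits(hierarchy, "label_hierarchy"))
  check_column(table, fine_col, "categorical")
  x <- table$data[[fine_col]]
  need <- setdiff(unique(x[!is.na(x)]), c(names(hierarchy), NO_MAPPED_CELLS))
  if (length(need) > 0) {
    stop("fine label(s) missing from hierarchy: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- unname(hierarchy[x])
  out[!is.na(x) & x == NO_MAPPED_CELLS] <- NO_MAPPED_CELLS
  table$data[[new_col]] <- out
  table$kinds[[new_col]] <- "categorical"
  table
}

#' Harmonize a study's labels onto a reference table
#'
#' Convenience composition of the cross-study linking procedure: build
#' the conditional [proportion_table()] from a shared-cell pairing of the
#' reference and study labels, then [probabilistic_assign()] study labels
#' onto every cell of the reference table.
#'
#' @param ref_table A [cell_table()] carrying `ref_col`.
#' @param shared_pairing A [cell_table()] carrying both `ref_col` and
#'   `study_col` on a shared cell set.
#' @param ref_col,study_col Column names as in [proportion_table()].
#' @param seed Integer seed for the probabilistic assignment.
#' @param new_col Name of the output column; defaults to `study_col` (the
#'   study's name).
#' @return `ref_table` with the harmonized study-label column added.
#' @export
harmonize_study <- function(ref_table, shared_pairing, ref_col, study_col,
                            seed, new_col = study_col) {
  pt <- proportion_table(shared_pairing, ref_col, study_col)
  probabilistic_assign(ref_table, pt, ref_col, new_col, seed)
}
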