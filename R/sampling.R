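#' Evenly subsample a cell table by cluster
#'
#' Caps table size while preserving small clusters, the mitigation used
#' when large data sets must be reduced (by default to at most 500,000
#' cells) to keep visualizations responsive without biasing cluster
#' composition. Quotas are computed by waterfilling: the even share is
#' `remaining cap / remaining clusters`; every cluster at or below the
#' share keeps all its records, the cap shrinks accordingly, and the
#' share is recomputed until only clusters above the share remain, which
#' then split the remaining cap equally (any indivisible remainder goes
#' one record at a time to the largest clusters, ties broken by name).
#' Within a cluster, records are selected uniformly at random at the
#' given seed. Missing cluster values form their own pseudo-cluster
#' `"(missing)"` rather than being silently dropped.
#'
#' @param table A [cell_table()].
#' @param cluster_col Categorical column defining the clusters.
#' @param cap Maximum number of records to retain (default 500,000); must
#'   be at least the number of clusters.
#' @param seed Integer seed for within-cluster selection.
#' @return A list with `table` (the subsampled [cell_table()], original
#'   row order preserved) and `plan` (a `subsample_plan` tibble: cluster,
#'   n_original, quota, n_retained; attributes `cap` and `seed`).
#'   Tables already within the cap are returned unchanged. Total retained
#'   is at most `cap` and at least `cap -` (number of clusters); no
#'   nonempty cluster is emptied.
#' @examples
#' ct <- make_numeric_fixture(n = 3000, k_clusters = 3, seed = 1)
#' sub <- even_subsample(ct, "cluster", cap = 300, seed = 7)
#' sub$plan
#' @export
even_subsample <- function(table, cluster_col, cap = 500000L, seed = 0L) {
  stopifnot(is_cell_table(table))
  check_column(table, cluster_col, "categorical")
  cap <- as.integer(cap)

  cl <- table$data[[cluster_col]]
  cl[is.na(cl)] <- "(missing)"
  counts <- table(cl)
  clusters <- names(counts)
  counts <- as.integer(counts)
  names(counts) <- clusters
  if (cap < length(clusters)) {
    stop("cap (", cap, ") is below the number of clusters (",
         length(clusters), ")", call. = FALSE)
  }

  if (n_cells(table) <= cap) {
    plan <- tibble::tibble(cluster = clusters, n_original = counts,
                           quota = counts, n_retained = counts)
    return(list(table = table, plan = new_subsample_plan(plan, cap, seed)))
  }

  quota <- waterfill_quotas(counts, cap)

  # uniform within-cluster selection, clusters visited in name order
  keep <- withr::with_seed(seed, {
    idx <- logical(length(cl))
    for (cluster in sort(clusters)) {
      members <- which(cl == cluster)
      q <- quota[[cluster]]
      idx[if (q >= length(members)) members
          else members[sample.int(length(members), q)]] <- TRUE
    }
    idx
  })

  out <- subset_cells(table, keep)
  retained <- table(cl[keep])
  plan <- tibble::tibble(
    cluster = clusters, n_original = counts,
    quota = unname(quota[clusters]),
    n_retained = as.integer(retained[clusters])
  )
  list(table = out, plan = new_subsample_plan(plan, cap, seed))
}

# Iterative waterfilling of an integer cap over cluster sizes.
waterfill_quotas <- function(counts, cap) {
  quota <- integer(length(counts))
  names(quota) <- names(counts)
  active <- names(counts)
  remaining <- cap
  repeat {
    share <- remaining / length(active)
    fits <- active[counts[active] <= share]
    if (length(fits) == 0) break
    quota[fits] <- counts[fits]
    remaining <- remaining - sum(counts[fits])
    active <- setdiff(active, fits)
    if (length(active) == 0) return(quota)
  }
  base <- remaining %/% length(active)
  extra <- remaining - base * length(active)
  quota[active] <- base
  if (extra > 0) {
    bump <- active[order(-counts[active], active)][seq_len(extra)]
    quota[bump] <- quota[bump] + 1L
  }
  quota
}

new_subsample_plan <- function(plan, cap, seed) {
  structure(plan, cap = cap, seed = seed,
            class = c("subsample_plan", class(plan)))
}

#' @export
print.subsample_plan <- function(x, ...) {
  cat("<subsample_plan> ", sum(x$n_retained), " of ", sum(x$n_original),
      " cells retained (cap ", attr(x, "cap"), ", ", nrow(x),
      " clusters)\n", sep = "")
  NextMethod()
}
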