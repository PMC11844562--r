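#' Toy pyramidal-neuron fixture
#'
#' Nine pyramidal neurons illustrating how size classifications shift
#' between two rounds of annotation: the first eight neurons were
#' classified into two groups by size (`size_v1`); the arrival of a ninth
#' neuron of intermediate size triggered a reclassification into three
#' groups (`size_v2`), so the original eight carry two different size
#' annotations and the ninth carries only the second. The ninth neuron's
#' `size_v1` is missing — it did not exist at first classification — so
#' the 8-cell overlap between the two annotations emerges from the data
#' model rather than from special-casing.
#'
#' @return A [cell_table()] with 9 records: categorical `size_v1` (two
#'   categories, missing for the ninth record), categorical `size_v2`
#'   (three categories, defined for all nine), and a numeric `size`
#'   consistent with both groupings.
#' @examples
#' toy <- make_toy_neurons()
#' sum(crosstab(toy, "size_v1", "size_v2"))  # 8 cells in both annotations
#' @export
make_toy_neurons <- function() {
  size <- c(10, 12, 14, 16, 30, 32, 34, 36, 22)
  cell_table(
    data.frame(
      cell_id = paste0("neuron_", 1:9),
      size = size,
      size_v1 = c(ifelse(size[1:8] < 20, "small", "large"), NA),
      size_v2 = ifelse(size <= 14, "small",
                       ifelse(size <= 25, "medium", "large"))
    )
  )
}

#' Specification of a planted two-taxonomy mixture
#'
#' Defines the ground truth for harmonization tests: reference labels
#' with cell counts and a row-stochastic mixing matrix giving, for each
#' reference label, the probability of each study label.
#'
#' @param counts Named integer vector: reference labels and their cell
#'   counts (all positive).
#' @param M Row-stochastic matrix; rownames are the reference labels (in
#'   the order of `counts`), colnames the study labels. Each row must sum
#'   to 1 within 1e-9.
#' @param seed Integer seed used when the fixture is materialized.
#' @return A `mixing_spec`.
#' @export
mixing_spec <- function(counts, M, seed = 0L) {
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts > 0))
  M <- as.matrix(M)
  if (is.null(rownames(M))) rownames(M) <- names(counts)
  if (is.null(colnames(M))) colnames(M) <- paste0("study_", seq_len(ncol(M)))
  stopifnot(identical(sort(rownames(M)), sort(names(counts))))
  bad <- abs(rowSums(M) - 1) > 1e-9
  if (any(bad) || any(M < 0)) {
    stop("mixing matrix rows must be probability distributions (rows ",
         "sum to 1 within 1e-9); offending: ",
         paste(rownames(M)[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(counts = as.integer(counts) |> stats::setNames(names(counts)),
                 M = M, seed = as.integer(seed)),
            class = "mixing_spec")
}

#' Materialize a planted reference/study label pairing
#'
#' Generates one record per planted cell: the reference label from the
#' spec's counts, and a study label drawn independently from the mixing
#' matrix row of that reference label at the spec's seed. Deterministic
#' at a fixed seed; different seeds change the label vector but never the
#' marginal reference counts.
#'
#' @param spec A [mixing_spec()].
#' @return A [cell_table()] with categorical columns `ref_label` and
#'   `study_label`.
#' @export
make_taxonomy_pair <- function(spec) {
  stopifnot(inherits(spec, "mixing_spec"))
  ref <- rep(names(spec$counts), spec$counts)
  n <- length(ref)
  u <- withr::with_seed(spec$seed, stats::runif(n))
  study <- character(n)
  for (lab in names(spec$counts)) {
    idx <- which(ref == lab)
    cum <- cumsum(spec$M[lab, ])
    cum[length(cum)] <- 1
    study[idx] <- colnames(spec$M)[findInterval(u[idx], cum,
                                                left.open = TRUE) + 1L]
  }
  cell_table(data.frame(cell_id = paste0("cell_", seq_len(n)),
                        ref_label = ref, study_label = study))
}

# Gaussian parameters of the numeric fixture: cluster centers are spaced
# CLUSTER_SPACING apart on the x axis and alternate +/- CLUSTER_SPACING/2
# on y; coordinates have unit SD; the extra feature is centered at
# FEATURE_GAP * cluster index with unit SD.
CLUSTER_SPACING <- 6
FEATURE_GAP <- 3
COORD_SD <- 1
FEATURE_SD <- 1

#' Numeric fixture with planted Gaussian clusters
#'
#' Emulates tables that mix categorical and numeric annotations — cluster
#' assignments alongside embedding coordinates or electrophysiological
#' measurements. Each record gets a cluster label, two coordinate columns
#' drawn from cluster-specific Gaussians, and one extra numeric feature
#' separated by cluster (see the documented module constants for the
#' planted means and SDs).
#'
#' @param n Number of records (`n >= k_clusters`).
#' @param k_clusters Number of clusters (`>= 1`); records are dealt to
#'   clusters round-robin so every cluster is nonempty.
#' @param seed Integer seed; identical calls regenerate bit-identical
#'   tables.
#' @return A [cell_table()] with categorical `cluster` and numeric `x`,
#'   `y`, `feature`.
#' @export
make_numeric_fixture <- function(n, k_clusters, seed = 0L) {
  stopifnot(n >= k_clusters, k_clusters >= 1)
  k_idx <- rep_len(seq_len(k_clusters), n)
  mu_x <- CLUSTER_SPACING * (k_idx - 1)
  mu_y <- CLUSTER_SPACING / 2 * ifelse(k_idx %% 2 == 0, 1, -1)
  vals <- withr::with_seed(seed, list(
    x = stats::rnorm(n, mu_x, COORD_SD),
    y = stats::rnorm(n, mu_y, COORD_SD),
    feature = stats::rnorm(n, FEATURE_GAP * k_idx, FEATURE_SD)
  ))
  cell_table(data.frame(
    cell_id = paste0("cell_", seq_len(n)),
    cluster = sprintf("cluster_%02d", k_idx),
    x = vals$x, y = vals$y, feature = vals$feature
  ))
}

#' Planted means of the numeric fixture
#'
#' Returns the per-cluster ground-truth means used by
#' [make_numeric_fixture()], for parameter-recovery tests.
#'
#' @inheritParams make_numeric_fixture
#' @return A tibble: cluster, mu_x, mu_y, mu_feature.
#' @export
numeric_fixture_truth <- function(k_clusters) {
  k_idx <- seq_len(k_clusters)
  tibble::tibble(
    cluster = sprintf("cluster_%02d", k_idx),
    mu_x = CLUSTER_SPACING * (k_idx - 1),
    mu_y = CLUSTER_SPACING / 2 * ifelse(k_idx %% 2 == 0, 1, -1),
    mu_feature = FEATURE_GAP * k_idx
  )
}
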