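# Independent brute-force oracles. These deliberately avoid the package's
# vectorized paths: plain per-record loops and set arithmetic.

# plain count matrix of a confusion_matrix, stripped of its class/attrs
cm_counts <- function(cm) {
  matrix(as.integer(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))
}

# crosstab by a double loop over records and label pairs
brute_crosstab <- function(a, b, rows, cols) {
  m <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  for (i in seq_along(a)) {
    if (is.na(a[i]) || is.na(b[i])) next
    m[a[i], b[i]] <- m[a[i], b[i]] + 1L
  }
  m
}

# Jaccard from explicit record-index sets
brute_jaccard <- function(a, b, rows, cols) {
  j <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  keep <- !is.na(a) & !is.na(b)
  for (r in rows) {
    set_a <- which(keep & a == r)
    for (cc in cols) {
      set_b <- which(keep & b == cc)
      uni <- union(set_a, set_b)
      j[r, cc] <- if (length(uni) == 0) 0 else
        length(intersect(set_a, set_b)) / length(uni)
    }
  }
  j
}

brute_row_fraction <- function(m) {
  out <- m * 0
  for (r in seq_len(nrow(m))) {
    tot <- sum(m[r, ])
    if (tot > 0) out[r, ] <- m[r, ] / tot
  }
  out
}

# a random small table with two categorical label columns and optional NAs
random_label_table <- function(n, n_a = 4, n_b = 3, p_na = 0.1) {
  a <- sample(paste0("A", seq_len(n_a)), n, replace = TRUE)
  b <- sample(paste0("B", seq_len(n_b)), n, replace = TRUE)
  a[stats::runif(n) < p_na] <- NA
  b[stats::runif(n) < p_na] <- NA
  cell_table(data.frame(cell_id = paste0("c", seq_len(n)),
                        lab_a = a, lab_b = b))
}

# 4-record pairing used in proportion-table examples: one reference label
# split 2:1:1 over three study labels
pairing_2_1_1 <- function() {
  cell_table(data.frame(
    cell_id = paste0("c", 1:4),
    supertype = rep("Sst_25", 4),
    celltype = c("SST", "SST", "IN_a", "IN_b")
  ))
}
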