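test_that("a column crossed with itself is diagonal with the value counts", {
  ct <- cell_table(data.frame(
    cell_id = paste0("c", 1:8),
    lab = c(rep("a", 3), rep("b", 5))
  ))
  cm <- crosstab(ct, "lab", "lab")
  expect_equal(unname(diag(cm)), c(5L, 3L))  # fallback order: by count
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
})

test_that("crosstab counts only records non-missing in both columns", {
  toy <- make_toy_neurons()
  cm <- crosstab(toy, "size_v1", "size_v2")
  expect_equal(sum(cm), 8L)  # the ninth neuron lacks the first annotation
  expect_equal(ncol(cm), 3L)
})

test_that("crosstab matches a brute-force record loop on random fixtures", {
  withr::with_seed(101, {
    for (rep in 1:25) {
      ct <- random_label_table(sample(20:200, 1))
      cm <- crosstab(ct, "lab_a", "lab_b")
      brute <- brute_crosstab(ct$data$lab_a, ct$data$lab_b,
                              rownames(cm), colnames(cm))
      expect_identical(cm_counts(cm)[rownames(brute), colnames(brute),
                                   drop = FALSE],
                       brute)
    }
  })
})

test_that("label order follows annotation info, then count-descending fallback", {
  ct <- cell_table(data.frame(
    cell_id = paste0("c", 1:6),
    lab = c("x", "x", "y", "y", "y", "z"),
    other = "o"
  ))
  # fallback: y (3) before x (2) before z (1)
  expect_equal(rownames(crosstab(ct, "lab", "other")), c("y", "x", "z"))
  info <- annotation_info(data.frame(column_name = "lab",
                                     value = c("z", "x")))
  # info-covered values first in info order, remainder by count
  expect_equal(rownames(crosstab(ct, "lab", "other", info)),
               c("z", "x", "y"))
})

test_that("jaccard view has identity pattern on self-crosstabs and handles nesting", {
  ct <- cell_table(data.frame(
    cell_id = paste0("c", 1:8),
    lab = c(rep("a", 3), rep("b", 5))
  ))
  j_self <- jaccard_view(crosstab(ct, "lab", "lab"))
  expect_equal(unname(j_self), diag(2))

  # an A-value of size 3 strictly inside a B-value of size 9
  nested <- cell_table(data.frame(
    cell_id = paste0("c", 1:12),
    a = c(rep("small", 3), rep("rest", 9)),
    b = c(rep("big", 9), rep("other", 3))
  ))
  j <- jaccard_view(crosstab(nested, "a", "b"))
  expect_equal(j["small", "big"], 3 / 9)
  expect_equal(j["small", "other"], 0)  # disjoint
})

test_that("jaccard and fraction views match brute-force set arithmetic", {
  withr::with_seed(202, {
    for (rep in 1:25) {
      ct <- random_label_table(sample(20:200, 1))
      cm <- crosstab(ct, "lab_a", "lab_b")
      expect_equal(unname(jaccard_view(cm)),
                   unname(brute_jaccard(ct$data$lab_a, ct$data$lab_b,
                                        rownames(cm), colnames(cm))))
      expect_equal(unname(fraction_view(cm, "row")),
                   unname(brute_row_fraction(cm_counts(cm))))
      # transposition symmetry of jaccard
      cm_t <- crosstab(ct, "lab_b", "lab_a")
      expect_equal(jaccard_view(cm_t),
                   t(jaccard_view(cm))[rownames(cm_t), colnames(cm_t)])
    }
  })
})

test_that("fraction views normalize each axis to 1 and zero out empty axes", {
  withr::with_seed(7, ct <- random_label_table(150))
  cm <- crosstab(ct, "lab_a", "lab_b")
  fr <- fraction_view(cm, "row")
  nonempty <- rowSums(cm) > 0
  expect_true(all(abs(rowSums(fr)[nonempty] - 1) < 1e-12))
  fc <- fraction_view(cm, "column")
  expect_true(all(abs(colSums(fc)[colSums(cm) > 0] - 1) < 1e-12))

  single <- cell_table(data.frame(cell_id = c("c1", "c2"),
                                  a = c("x", "y"), b = "only"))
  expect_true(all(fraction_view(crosstab(single, "a", "b"), "row") == 1))
})

test_that("river models satisfy link/node conservation per adjacent pair", {
  toy <- make_toy_neurons()
  rm2 <- river_model(toy, c("size_v1", "size_v2"))
  expect_equal(sum(rm2$nodes$column == "size_v2"), 3)  # three groups

  # identical columns: one link per category, link count = category count
  ct <- cell_table(data.frame(cell_id = paste0("c", 1:10),
                              a = rep(c("x", "y"), 5)))
  ct$data$a2 <- ct$data$a
  ct$kinds[["a2"]] <- "categorical"
  rm_id <- river_model(ct, c("a", "a2"))
  expect_equal(nrow(rm_id$links), 2)
  expect_equal(sort(rm_id$links$count), c(5L, 5L))

  # three-column chain: links equal crosstabs; conservation per pair
  withr::with_seed(33, {
    ct3 <- random_label_table(300)
    ct3$data$lab_c <- sample(c("C1", "C2"), 300, replace = TRUE)
    ct3$kinds[["lab_c"]] <- "categorical"
    rm3 <- river_model(ct3, c("lab_a", "lab_b", "lab_c"))
    for (pair in list(c("lab_a", "lab_b"), c("lab_b", "lab_c"))) {
      cm <- crosstab(ct3, pair[1], pair[2])
      links <- rm3$links[rm3$links$from_column == pair[1], ]
      expect_equal(nrow(links), sum(cm > 0))
      for (i in seq_len(nrow(links))) {
        expect_equal(links$count[i],
                     cm_counts(cm)[links$from_value[i], links$to_value[i]])
      }
      # node conservation restricted to pairwise-complete records
      out_sums <- tapply(links$count, links$from_value, sum)
      expect_equal(as.numeric(out_sums[rownames(cm)][rowSums(cm) > 0]),
                   as.numeric(rowSums(cm)[rowSums(cm) > 0]))
    }
  })
  expect_error(river_model(toy, "size_v1"), "at least 2")
})

test_that("crosstab totals are invariant to record order and zero-record filtering", {
  withr::with_seed(44, ct <- random_label_table(120))
  cm <- crosstab(ct, "lab_a", "lab_b")
  perm <- withr::with_seed(45, sample(n_cells(ct)))
  shuffled <- cell_table(
    tibble::add_column(ct$data[perm, ], cell_id = ct$cell_id[perm],
                       .before = 1))
  cm_perm <- crosstab(shuffled, "lab_a", "lab_b")
  expect_identical(cm_counts(cm), cm_counts(cm_perm)[rownames(cm), colnames(cm)])

  # removing zero records (an always-true filter) changes nothing
  kept <- apply_filter_set(ct, filter_set(
    categorical_filter("lab_a", unique(stats::na.omit(ct$data$lab_a)))))
  dropped_na <- sum(is.na(ct$data$lab_a))
  expect_equal(sum(crosstab(kept, "lab_a", "lab_b")), sum(cm))
  expect_equal(n_cells(kept), n_cells(ct) - dropped_na)
})

test_that("value breakdowns equal the focal row of a filtered crosstab", {
  withr::with_seed(66, ct <- random_label_table(200))
  info <- annotation_info(data.frame(
    column_name = "lab_b", value = c("B1", "B2", "B3"),
    direction = c("down", "up", "unchanged")))
  bd <- value_breakdown(ct, "lab_a", "A1", "lab_b", info)
  cm <- crosstab(ct, "lab_a", "lab_b")
  row <- cm_counts(cm)["A1", ]
  row <- row[row > 0]
  got <- stats::setNames(bd$entries$count, bd$entries$value)
  expect_equal(got[names(row)], row[names(row)], ignore_attr = TRUE)
  expect_equal(sum(bd$entries$count),
               sum(!is.na(ct$data$lab_b) & !is.na(ct$data$lab_a) &
                     ct$data$lab_a == "A1"))
  expect_equal(bd$entries$direction,
               direction_of(info, "lab_b", bd$entries$value))

  # a focal value mapping entirely to one target value
  mono <- cell_table(data.frame(cell_id = paste0("c", 1:10),
                                a = "focal", b = "target"))
  bd_mono <- value_breakdown(mono, "a", "focal", "b")
  expect_equal(nrow(bd_mono$entries), 1)
  expect_equal(bd_mono$entries$count, 10L)

  expect_warning(bd_empty <- value_breakdown(ct, "lab_a", "nope", "lab_b"),
                 "does not occur")
  expect_equal(bd_empty$n_focal, 0L)
  expect_equal(nrow(bd_empty$entries), 0)
})

test_that("direction concordance tallies study columns like the multi-study use case", {
  # nine "study" columns; in six of them every matched value is tagged down
  n_study <- 9
  n_down <- 6
  ct_df <- data.frame(cell_id = paste0("c", 1:40),
                      supertype = rep(c("Sst_25", "Other"), each = 20))
  info_rows <- list()
  for (k in seq_len(n_study)) {
    col <- sprintf("study_%d", k)
    ct_df[[col]] <- rep(c(sprintf("SST_like_%d", k), "NotSst"), each = 20)
    info_rows[[k]] <- data.frame(
      column_name = col,
      value = sprintf("SST_like_%d", k),
      direction = if (k <= n_down) "down" else "unchanged")
  }
  ct <- cell_table(ct_df)
  info <- annotation_info(do.call(rbind, info_rows))
  bd <- value_breakdown(ct, "supertype", "Sst_25",
                        sprintf("study_%d", seq_len(n_study)), info)
  tally <- direction_concordance(bd, info, weighting = "by_value")
  expect_equal(nrow(tally), n_study)
  expect_equal(sum(tally$dominant == "down"), n_down)
  # per column, counts sum to the number of distinct matched values
  expect_true(all(tally$up + tally$down + tally$unchanged +
                    tally$unknown == 1))

  # all tags unknown -> dominant unknown everywhere
  bd_unk <- value_breakdown(ct, "supertype", "Sst_25",
                            sprintf("study_%d", 1:3))
  tally_unk <- direction_concordance(bd_unk)
  expect_true(all(tally_unk$dominant == "unknown"))

  # single matched value tagged up -> up-dominant with counts {up: 1}
  one <- cell_table(data.frame(cell_id = paste0("c", 1:5),
                               a = "focal", b = "tgt"))
  info_up <- annotation_info(data.frame(column_name = "b", value = "tgt",
                                        direction = "up"))
  t_up <- direction_concordance(value_breakdown(one, "a", "focal", "b",
                                                info_up))
  expect_equal(t_up$dominant, "up")
  expect_equal(t_up$up, 1)

  # by_cell weighting uses record counts
  t_cell <- direction_concordance(bd, info, weighting = "by_cell")
  expect_true(all(t_cell$down[seq_len(n_down)] == 20))
})

test_that("river models serialize to the documented JSON schema", {
  rm2 <- river_model(make_toy_neurons(), c("size_v1", "size_v2"))
  path <- withr::local_tempfile(fileext = ".json")
  write_river_model(rm2, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(names(doc), c("columns", "nodes", "links"))
  expect_equal(doc$columns, c("size_v1", "size_v2"))
  expect_equal(sum(doc$links$count), 8)
})
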