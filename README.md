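# annotlink

Single-cell and Patch-seq studies each classify their cells into their own
cell type taxonomy, so the same neuron may be an "Sst_25" supertype in one
study, an "SST" interneuron in another, and unannotated in a third.
`annotlink` is a headless R toolkit for comparing, linking and harmonizing
such categorical cell annotations across studies. It is aimed at
computational biologists who have cell-level annotation tables (cell type
assignments, anatomic structures, QC metrics — not expression matrices) and
want reproducible, scriptable versions of the statistics behind
annotation-comparison visualizations: confusion matrices, river (alluvial)
plots, per-value breakdowns colored by disease direction, and probabilistic
cross-study label transfer.

## What it computes

Let two categorical annotations over the same cells define record sets
$A_i$ (cells with value $i$ in column A) and $B_j$. The core statistics
are:

- **Confusion matrix** — counts $n_{ij} = |A_i \cap B_j|$ over cells
  non-missing in both columns, with three derived views:
  row/column fractions $n_{ij}/n_{i\cdot}$ (each nonempty row sums to 1)
  and **Jaccard similarity**
  $J_{ij} = n_{ij} / (n_{i\cdot} + n_{\cdot j} - n_{ij})$.
- **River model** — for an ordered list of columns, category nodes per
  column and links between adjacent columns whose weights are the pairwise
  crosstab; link counts are conserved per adjacent pair.
- **Probabilistic harmonization** — from a shared-cell pairing of a
  reference label column $s$ and a study label column $c$, the conditional
  proportion table $p(c \mid s) = n_{sc}/n_{s}$; every reference cell then
  receives an independent draw from $p(\cdot \mid s)$, and reference labels
  never co-observed with a study label get the reserved label
  `noMappedCells` with probability 1. Broad labels are inferred from fine
  labels through an explicit hierarchy.
- **Even subsampling by cluster** — a waterfilling rule that caps a table
  (default 500,000 cells) while keeping every cluster nonempty: clusters at
  or below the even share are kept whole and the remaining cap is split
  equally among the larger ones.

Tables are read from csv, gzipped csv, feather, or h5ad (per-cell metadata
only); an optional annotation-info table supplies display order,
descriptions, and the direction of abundance change with disease
(`up`/`down`/`unchanged`/`unknown`) used to color breakdowns and tally
cross-study concordance.

## Worked example

Nine pyramidal neurons: eight were first classified into two size groups
(`size_v1`); adding a ninth of intermediate size forced a reclassification
into three groups (`size_v2`).

```r
library(annotlink)
toy <- make_toy_neurons()
cm <- crosstab(toy, "size_v1", "size_v2")
cm
#> <confusion_matrix> size_v1 x size_v2 (8 cells)
#>       large small medium
#> large     4     0      0
#> small     0     3      1
```

Only 8 cells carry both annotations (the ninth did not exist at first
classification). The matrix shows the old "small" group splitting: three
cells stay "small" and one becomes "medium". The river model carries the
same links in plot-ready form:

```r
model <- river_model(toy, c("size_v1", "size_v2"))
model$links
#> # A tibble: 3 × 5
#>   from_column from_value to_column to_value count
#> 1 size_v1     large      size_v2   large        4
#> 2 size_v1     small      size_v2   small        3
#> 3 size_v1     small      size_v2   medium       1
render_river(model, plot_style(), "river.png")
```

Harmonization starts from a shared-cell pairing. Here a reference
supertype whose cells were called `SST` twice and `IN_a`/`IN_b` once each:

```r
pairing <- cell_table(data.frame(
  cell_id = paste0("c", 1:4),
  supertype = rep("Sst_25", 4),
  celltype = c("SST", "SST", "IN_a", "IN_b")))
proportion_table(pairing, "supertype", "celltype")
#>   ref_label study_label probability
#> 1 Sst_25    SST                0.5
#> 2 Sst_25    IN_a               0.25
#> 3 Sst_25    IN_b               0.25
```

`probabilistic_assign()` (or the `harmonize_study()` convenience wrapper)
then writes a study-label column onto any table carrying the reference
labels, drawing per cell from these proportions at a fixed seed.

## Command line

Every operation is exposed through a single entry point installed with the
package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","annotlink.R",package="annotlink"))')" \
    filter --in cells.csv --keep class=Endo,Micro --range n_genes=500:8000 --out subset.csv
```

Subcommands: `convert`, `validate`, `filter`, `compare`, `river`,
`breakdown`, `harmonize`, `subsample`, `fixtures`, `render`; global flags
`--seed`, `--log-level`, `--config`.

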