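---
title: "Comparing and harmonizing cell type annotations across studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing and harmonizing cell type annotations across studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annotlink)
```

## The problem

Every single-cell study invents, or adapts, its own cell type taxonomy.
When several studies profile overlapping tissue — cortical studies of
Alzheimer's disease are the motivating case — the same biological
population ends up with different names, different resolutions, and
different reported changes in abundance with disease. `annotlink` works
entirely at the level of *cell annotation tables*: one row per cell,
categorical or numeric annotation columns, no expression data. Its job is
to make the relationships between such annotation columns quantitative and
reproducible.

Two inputs drive everything:

* the **cell table** — unique `cell_id` per row plus annotation columns.
  A column is tagged *numeric* iff every non-missing entry parses as a
  finite real; anything else is *categorical*. Integer-coded cluster ids
  that should stay categorical can be forced by a per-column override
  (argument or YAML config). In csv input the empty string and the literal
  `NA` are missing; on write, missing is always the empty string, which
  keeps write→load round trips stable.
* the optional **annotation-info table** — per (column, value): display
  order (file row order within each column; ties are an error),
  description, and a *direction* of abundance change with disease drawn
  from the fixed vocabulary `up`, `down`, `unchanged`, `unknown`. Any
  other string is mapped to `unknown` with a warning rather than invent
  new categories silently. Values not covered by the info table are
  ordered by descending count with lexicographic tie-breaks, after the
  covered ones — a deterministic fallback for tables shipped without
  metadata.

For h5ad input only the per-cell metadata (`obs`) and its index are read;
this package is annotation-centric and never touches the expression
matrix.

## Filtering semantics

Filters are conjunctive across columns, at most one filter per column.
Categorical filters keep rows whose value is in the included set, XOR an
invert flag; numeric filters are closed intervals (both ends inclusive,
matching slider-style selection). A row missing a filtered value fails
that filter *in both invert states*: membership cannot be asserted either
way for a missing value, and fixing this rule makes retained counts
reproducible. Consequences worth knowing: inverted and non-inverted counts
sum to the table size only when the column has no missing values, and
filtering is idempotent.

## Comparison statistics

All pairwise statistics use the records non-missing in **both** columns
involved — pairwise-complete, not listwise. In a river model over three or
more columns, each adjacent pair therefore uses its own complete set, and
count conservation (node count = sum of incident link counts) holds per
adjacent pair rather than globally. We chose pairwise deletion because it
maximizes usable data when studies annotate different subsets of cells;
the conservation property is stated accordingly and tested as such.

* Confusion matrix: $n_{ij}$ counts of column-A value $i$ against
  column-B value $j$.
* Row/column fraction views divide by the axis total; an empty axis stays
  all-zero instead of producing NaN. Nonempty rows sum to 1 within
  1e-12 — the tolerance is pure floating-point slack, not a model
  parameter.
* Jaccard view: $J_{ij} = n_{ij}/(n_{i\cdot}+n_{\cdot j}-n_{ij})$, with
  $J = 0$ when the union is empty (that only happens for labels filtered
  down to zero records; rendering it as "no relationship" is the sensible
  display convention).
* Value breakdowns restrict to one focal value and tabulate every other
  requested column, attaching each value's direction tag. Direction
  concordance then tallies, per compared column, how many matched values
  are tagged up/down/unchanged/unknown — either one vote per value
  (`by_value`) or weighted by cell count (`by_cell`) — and calls the
  dominant direction, with ties reported as `unknown` rather than
  arbitrated. This is the machinery behind "this population decreased in
  k of n studies" summaries.

## Probabilistic harmonization

Cross-study label transfer consumes a *shared-cell pairing*: a table in
which the same cells carry both the reference labels (e.g., mapped
supertypes) and a study's own labels. Cells missing either label are
dropped. For each reference label $s$ the conditional proportions
$p(c \mid s) = n_{sc}/n_s$ form a probability distribution; reference
labels that occur in the pairing's reference column but are never
co-observed with a study label get the reserved label `noMappedCells`
with probability 1 — typically neuronal types compared against a
glia-only study. The reserved label is also what a cell receives when its
reference label is entirely unknown to the proportion table (with a
warning, not an error, mirroring how taxonomy mismatches are handled in
practice), and input tables that use `noMappedCells` as a genuine
category draw a validation warning.

Assignment draws one study label per cell, independently, from
$p(\cdot \mid s)$. The generator is seeded once per call and uniform
deviates are consumed in table row order, so identical inputs and seed
give a bit-identical column; nothing else about the table is touched.
Broad-label inference is a deterministic lookup through an explicit
fine→broad hierarchy that must cover every observed fine label
(`noMappedCells` and missing pass through). Coarsening commutes with
assignment in distribution — assigning fine labels and then coarsening is
distributionally equal to coarsening the pairing first — which the test
suite checks empirically at fixed seeds.

Whether to subsample before or after assignment is left to the pipeline;
the command-line `harmonize` applies the proportion table to whatever
reference table it is given, so users who subsample first get
subsample-then-assign.

## Even subsampling by cluster

Large tables are capped (default 500,000 records) to keep downstream
visualization responsive. A plain uniform subsample would thin rare
populations into invisibility, so quotas are computed by **waterfilling**:
the even share is `remaining cap / remaining clusters`; every cluster at
or below the share is kept whole; the share is recomputed on what remains;
when only clusters above the share are left they split the remaining cap
equally, the indivisible remainder going one record at a time to the
largest clusters (ties by name). The result: no nonempty cluster is ever
emptied, the total is never above the cap and never more than one-per-
cluster below it, and equal clusters get exactly equal quotas. Selection
within a cluster is uniform at the caller's seed; changing the seed
changes membership but never the per-cluster counts. Missing cluster
values are subsampled as their own `"(missing)"` pseudo-cluster because
silently dropping unlabeled cells would bias totals.

## What the fixtures emulate — and what they do not

The fixtures module generates every input the tests use:

* `make_toy_neurons()` — the nine-neuron reclassification story: eight
  neurons in two size groups, a ninth of intermediate size forcing three
  groups. The ninth neuron's first-round annotation is *missing* (it did
  not exist then), so the 8-cell overlap between the annotations emerges
  from missing-data semantics, not special-casing. The numeric sizes are
  arbitrary but consistent with both groupings, since only the grouping
  structure matters.
* `make_taxonomy_pair()` — a planted row-stochastic mixing matrix between
  a reference and a study taxonomy, materialized cell by cell at a fixed
  seed. This is the ground truth for harmonization recovery tests.
* `make_numeric_fixture()` — Gaussian clusters for two coordinate columns
  plus one separated feature (module constants: cluster centers 6 apart,
  unit SDs, feature gap 3), standing in for embeddings, spatial
  coordinates, or electrophysiology.

These fixtures capture label structure, missingness, and sampling noise.
They do **not** emulate real data's doublets, batch effects, hierarchical
label noise (mislabeled cells correlated within donors), or the fact that
real taxonomies disagree more at boundaries than in cores. Passing tests
therefore demonstrate that the statistics and the assignment machinery are
computed correctly, not that harmonized labels are biologically right for
any particular pair of studies.

## Numerical and design choices

* Proportion tables validate to 1 within 1e-12 per reference label;
  assignment guards the top of each cumulative distribution at exactly 1
  so a uniform deviate can never fall off the end.
* Test problem sizes were chosen to make statistical checks sharp but
  cheap: 50,000 cells per reference label puts 3 binomial standard errors
  at about half a percentage point, and the 100-seed battery's failure
  bound is the 0.999 binomial quantile at the nominal two-sided
  3-sigma rate — computed, not hard-coded.
* Renderers (ggplot2) never mutate inputs and can emit their plot-ready
  numbers (node/ribbon positions, dot sizes, jittered coordinates) as
  csv/json sidecars; tests assert on those numbers, because pixel
  comparisons are brittle across graphics backends. Dot sizes scale
  linearly between a documented minimum and maximum; bee-swarm jitter is
  seeded from the style object.
* River ribbon geometry (stacked nodes, links slotted in model order) is
  computed in-package; the layout is presentation plumbing, and the
  tested contract is the model itself.

## Known limitations

Only one grouping column is supported for subsampling; no statistical
tests of association are computed (by design — the comparisons are
descriptive); csv cannot carry column-kind metadata, so a categorical
column whose values all look numeric needs its override re-supplied after
a csv round trip (feather preserves kinds natively); and h5ad support is
read-only and metadata-only.
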