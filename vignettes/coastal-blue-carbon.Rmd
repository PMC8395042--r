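---
title: "Methods: coastal blue-carbon accounting from land-cover transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coastal blue-carbon accounting from land-cover transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coastCarbon)
```

## The accounting model

`coastCarbon` treats a coastal study area as a fixed mask of square cells,
each carrying one of ten land-cover codes at each observation date:
offshore waters (1), tidal flat (2), coastal marsh (3), grassland (4),
river and lake (5), aquaculture fish pond (6), paddy field (7), reservoir
(8), construction land (9) and rainfed cropland (10). Codes 2, 3 and 5 form
the natural-wetland group, 6–8 the artificial wetlands, 4, 9 and 10 other
land, and 1 its own waters group. Grassland participates in natural
succession and erosion even though it is grouped with "other land" for
storage summaries; the grouping and the process taxonomy are deliberately
separate lookup tables.

Carbon is booked with a pool model: each class *i* has an aboveground,
belowground, dead-matter and soil carbon density (Mg/ha) whose sum is the
class total `C_i`, and the stock of a map is `C_tot = Σ_i C_i · S_i` with
`S_i` the class area in hectares. Sequestration over a period is the
later-minus-earlier difference of `C_tot`. Two strong assumptions are
inherited from this bookkeeping style: carbon density is constant within a
class, and storage changes *immediately* when the class changes — no
multi-decade relaxation toward a new steady state. Both matter when
interpreting magnitudes per hectare; neither affects the transition or
chain machinery.

The shipped density table is the published coastal table this package's
fixtures come from. Its printed totals disagree with the printed pool sums
for three classes (coastal marsh 32.4 vs 64.0, paddy field 25.5 vs 51.9,
rainfed cropland 20.5 vs 41.0 Mg/ha). The default mode uses the printed
`c_total` column, because that column is what the storage formula consumes
and silently "fixing" published inputs would fabricate data; `strict =
TRUE` recomputes totals from pools and warns, and `validateInputs()`
reports the three rows so the discrepancy is always visible. Which
convention the original analysis fed to its software is unknowable; both
are provided and clearly labeled.

## Transition matrices

`transitionMatrix()` tallies exact integer cell counts for each ordered
code pair and scales by the cell area; areas are held at full precision
and rounded to the 0.01 km² of published tables only when written to CSV.
Nodata cells (sentinel 0) are excluded everywhere and the nodata mask must
be identical across dates, which makes total area a conserved quantity —
the per-period totals of one series are equal by construction, a property
the tests assert. The CSV layout fixes one canonical column order (codes
1–10, explicit class-name labels) with a trailing transfer-out column and
transfer-in row; published variants of the same table sometimes swap
column order between blocks, which label-driven reading makes harmless.

`materializeFromMatrix()` inverts the tally: given a matrix whose entries
are integral multiples of the cell area, it lays out a congruent raster
pair (arbitrary row-major fill) whose recomputed matrix equals the input
exactly. With 100 m cells every 0.01-km² printed value is one cell, so
published tables can be turned into exact fixtures. One marginal cell of
the shipped 2000–2009 block is internally inconsistent in the original
table (grassland transfer-in prints 5.97 km² over column cells summing to
5.89 km²); the fixture realizes the cells, so the re-derived marginal is
5.89 — the package reproduces the table's cells, not its arithmetic slips.

## Driving-process chains

Each ordered code pair maps to exactly one process step: accretion
(1→2, 1→3, 5→2, 5→3), succession (2→3, 2→4, 3→4), regressive succession
(3→2), erosion (2→1, 3→1, 4→1), reclamation (any of 1–5 → any of 6–10),
restoration (any of 6–10 → any of 1–5), Stable on the diagonal. The
remaining 29 pairs (e.g. 9→6, 2→5) belong to no named process; they are
kept as explicit "U" (unclassified) steps rather than being silently
assigned, because the taxonomy's source never states how such pixels were
treated. Chains bearing U steps are excluded from process aggregation by
default and reported separately (`includeUnclassified = TRUE` keeps them).

A pixel's chain is its interval steps with Stable dropped and consecutive
duplicates collapsed, so "Mono" means one *distinct* process, not one
interval — published chain inventories contain no repeated-letter chains,
which is consistent with either collapsing or non-recurrence; collapsing
is the choice that makes the inventory well-defined either way. Categories
combine chain length with the sign of the net carbon change: Mono±,
Multiple±. Per *chain record* the sign is that of the aggregate change;
per *cell* (the category raster) each cell's own ΔC decides, since a map
is spatial while a table row is a summary. A net change of exactly zero is
the boundary case "Neutral", reported but never merged into ±; unchanged
cells are "Stable".

## Natural-breaks carbon levels

Per-class total densities are classified into k = 4 levels (Lowest, Lower,
Higher, Highest) by the exact Fisher–Jenks dynamic program — minimizing
total within-class sum of squared deviations over contiguous classes of
the sorted values. The implementation is exact, not the common greedy
approximation, and deterministic: among equal-cost partitions the one with
the smallest leftmost break index wins (the DP updates only on strict
improvement while scanning breaks in ascending order). The test suite
checks it against exhaustive enumeration for every n ≤ 12. With ten
classes this is instantaneous; the DP is O(k·n²) and comfortable far
beyond that.

## Process × year matrix and clustering

For every chain, the carbon stored by its pixels is evaluated at each date
(density of the date's code × cell area, summed), giving a chains × dates
matrix. Each date column is z-scored across chains, `(x − μ)/σ`, with the
*population* standard deviation (divide by n) as the default — the bare
formula names σ without a sample correction — and an `sample = TRUE`
switch for parity with heatmap tooling that defaults to n − 1. A
zero-variance column becomes all zeros; a single-row matrix is an error
since σ is undefined.

Rows are then clustered agglomeratively under Euclidean distance via
`stats::hclust`. The linkage is configurable (complete, average, single)
with complete as default, the common clustered-heatmap default; the
distance, not the linkage, is the method's stated choice, so all three are
exposed rather than guessed. Year columns stay in chronological order by
default. Tests verify the merge sequence against a brute-force
nearest-pair oracle on random matrices, where continuous values make ties
a measure-zero event; exact-tie behavior follows `hclust`. Exports are a
CSV of the normalized matrix in leaf order and a JSON dendrogram (labels,
merge pairs, heights, leaf order); `plotProcessHeatmap()` is a thin
`pheatmap` veneer over the same objects.

## The synthetic coastal generator

`generateSeries()` emulates the statistical structure the analysis
assumes: a land–sea gradient (a settled strip of paddy/construction/
cropland, then marsh and tidal-flat bands, then open water) advanced
through intervals in which, in fixed order, water accretes to flat along
the shoreline, flats and marshes succeed landward (2→3, 3→4), marsh
degrades (3→2), exposed cells erode back to water, near-shore cells are
reclaimed into one of the artificial/other classes, and artificial cells
are restored to flat or marsh. Eligibility is judged on the
start-of-interval state, each cell changes at most once per interval
(mirroring one process step per period), shoreline contact uses
4-adjacency, and all draws come from a single seeded stream consumed in
raster row-major order — the same scenario and seed reproduce the series
bit for bit.

No published rates exist for the real processes, so the defaults
(accretion 0.40, succession 0.30, regressive succession 0.05, erosion
0.10, reclamation 0.15, restoration 0.05 per interval; reclamation targets
0.30/0.25/0.10/0.20/0.15 over ponds/paddies/reservoirs/construction/
cropland; reach 15 columns; 80 × 120 cells at 30 m, four dates) were
chosen once as plausible for a prograding, progressively reclaimed delta
coast at decadal intervals, and are not revisited. The generator
reproduces the *kind* of data the method consumes — contiguous class
bands, one-directional shoreline movement, process chains with known
ground truth — but not the geometry, autocorrelation structure or class
abundances of any real coast, so passing tests demonstrate correct
bookkeeping and classification, not realism of any particular rate.

## Numerical and interface choices

* Nodata sentinel is 0; the study mask is fixed across dates (the union of
  mapped extents when assembling real series), making area and the
  telescoping identity `seq(t0,t1) + seq(t1,t2) + seq(t2,t3) =
  seq(t0,t3)` exact.
* Rasters are ESRI ASCII grids (single-band integer, row 1 northernmost);
  the format is plain text, diffable and sufficient for categorical maps.
* Areas: km² in matrices, ha in process records; carbon in Mg with ×10⁴ Mg
  convenience columns in pipeline summaries.
* All pipeline randomness flows from the single config seed; the manifest
  records config, seed and package version, and identical configs produce
  byte-identical text outputs.

Test problem sizes were chosen to exercise every property well inside a
laptop's patience: random 20 × 20 grids against the per-cell tally oracle,
6 × 4 matrices against the O(n³) clustering oracle, n ≤ 12 exhaustive
natural-breaks enumeration, 100 × 100 cells (10⁴ draws) for rate-recovery
checks at three standard errors, and the full published blocks
(≈ 87,600 changed cells for 1990–2015) for exact marginal recovery.

## Limitations

The headline storage and sequestration totals of the original study are
not reproducible from its published tables: they require the classified
rasters, which were never deposited, and the printed density table's
internal inconsistency means no density convention recovers the printed
sequestration values from the printed transition matrices alone. The
package therefore anchors its exactness claims on what *is* printed —
transition blocks and density pools — and on property suites; the
changed-area sequestration it computes from a materialized block covers
the transfers only, not the unchanged diagonal that a full-map total
includes. Carbon dynamics (gradual accumulation, eddy-covariance
calibration), map accuracy assessment and any valuation are out of scope.
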