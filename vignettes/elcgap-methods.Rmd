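---
title: "Ecogeographical gap analysis with elcgap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecogeographical gap analysis with elcgap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elcgap)
library(dplyr)
```

## The problem

Genebanks conserve crop wild relatives (CWR) as *accessions*: germplasm
samples with passport data recording where each was collected. Floristic
databases and other *external sources* report where the species actually
occur. A germplasm collection is ecogeographically representative when its
accessions cover the range of environmental — hence putatively adaptive —
scenarios in which the species grows. `elcgap` implements a gap-analysis
workflow that (1) cleans the occurrence data, (2) derives a per-species
Ecogeographical Land Characterization (ELC) map of the territory,
(3) identifies the populations reported by external sources that the
collection does not yet represent, spatially and ecogeographically, and
(4) shortlists those populations most likely to carry drought and salinity
tolerance.

Every stage operates on tidy tibbles and the whole workflow is driven by
`run_pipeline()`; the synthetic-landscape generator supplies inputs with
known ground truth so that each stage is testable without downloading
rasters or occurrence data.

## Occurrence quality control

Records arrive in an MCPD-style CSV dialect. Coordinates are parsed from
their *textual* representation because the precision filter depends on how
many decimals were declared, not on the float value: an external record is
removed when its decimal-degree coordinates have fewer than two decimals in
both axes, when it has no locality text, or when it came from a UTM square
coarser than 1 km. Accessions are never removed by this rule — their
coordinates come from collecting missions and are curated upstream.

Spatial duplicates follow a 1-km population concept: two records of the
same species and source class less than 1 km apart (great-circle, sphere
radius 6371.0088 km) are one population. The greedy scan retains records in
order of quality score (ties by record id), so the best-documented record
of a cluster survives. The retained set is pairwise at least 1 km apart and
every removed record is within 1 km of a retained one — a contract the
tests verify against a brute-force all-pairs oracle, independent of the
scan order. Records at exactly 1.0 km are kept: duplicates are strictly
*closer than* 1 km.

Georeferencing quality is a 0–100 composite of three sub-scores
(coordinate precision, administrative agreement by point-in-polygon,
locality completeness); records scoring strictly above 80 enter the
analysis. The composite is a deliberately simple, monotone stand-in for a
full georeferencing audit: the downstream workflow uses only the
thresholded score, so any scorer with the same monotonicity can be plugged
in. When no administrative boundaries are supplied, that sub-score is
skipped and the remaining two are averaged.

Reading of the precision rule: the phrase "fewer than two decimals in both
axes or no textual description" is grouped as an OR of removal conditions
(coarse-in-both, no-locality, coarse-UTM). This grouping mirrors how
curation reports count a single "low accuracy" bucket. Deduplication is
applied within species and source class only; accessions and externals are
never deduplicated against each other, since the gap analysis needs both
sides of coincident pairs.

## Variable selection

Raster values are extracted at each record's containing cell; the grid is
treated as half-open intervals `[west, east) x [south, north)` so a point
on a shared edge belongs to exactly one cell. Records on nodata cells are
excluded and listed, never silently dropped.

Variable importance per ecogeographical component (bioclimatic, edaphic,
geophysic) uses an unsupervised random-forest contrast: each column of the
site-by-variable matrix is independently permuted to build a "synthetic"
class with the same marginals but no joint structure, and a forest of 500
trees is trained to separate real from synthetic rows. The permutation
importance (mean decrease in accuracy), averaged over 5 seeded
repetitions, ranks variables by how much joint, site-structured signal
they carry. This is one of the standard ways to run random forests without
a response variable; it is clearly a design choice — a documented
alternative is to pre-cluster the sites and classify the clusters — and
the ranking function is isolated so it can be swapped.

The ranking is truncated to the top 15 variables, then scanned in rank
order: a pair with Pearson |r| > 0.50 and two-sided p < 0.05 (t statistic,
n−2 df) loses its lower-ranked member, and a dropped variable cannot drop
others. Truncate-then-prune is used because redundancy only matters among
the variables that can still be selected. The final set is the top three
bioclimatic, three edaphic and two geophysic survivors, plus latitude and
longitude appended as two extra geophysic variables: including position
pulls the eventual map categories into spatially aggregated patches.

## The ELC map

Each component's selected variables are z-standardized over **all land
cells of the territory** — the map must characterize the whole study area,
not just occurrence sites — and mixed units (mm, °C, dS/m, degrees) would
otherwise dominate the distances. K-means is run for k = 1..8 with at
least 10 restarts per k, keeping the best within-group sum of squares
(WSS); the per-k WSS sequence must come out non-increasing or the run
fails. The number of clusters follows the elbow rule: the chosen k is the
smallest n whose relative WSS decrease to n+1 falls below 50%,

$$\frac{WSS(n) - WSS(n+1)}{WSS(n)} < 0.5,$$

with two defined edge cases: a zero WSS counts as a decrease of 0 (stop
there), and if every decrease up to k = 8 is at least 50% the cap k = 8 is
chosen. The criterion is read as the relative drop of WSS itself between
consecutive k, which is the literal reading of "the decrease in the
intra-group sum of squares ... is less than 50%".

The ELC category of a land cell is the triple of its component cluster
labels. Observed triples get consecutive ids in lexicographic
(bioclimatic, edaphic, geophysic) order — a reproducible legend — and a
cell where any component is nodata is nodata. Occurrence records are then
assigned categories by the same containing-cell lookup; records in the sea
margin get category 0 and are excluded from representativeness.

## Gap analysis and priority ranking

An external record is a **spatial gap** when it is strictly more than 1 km
from every accession of its species (mirroring the strict <1 km duplicate
rule). A category is an **ecogeographical gap** when at least one external
record occurs there and no accession does. Collection priority ranks run
1–10. The published workflow defines only the anchor property: ranks 1–4
are exactly the records in unrepresented categories ("priority
ecogeographical gaps"). The scoring inside those bands is not published,
so `elcgap` uses a documented stand-in: unrepresented categories rank by
the quartile of their territory share among unrepresented categories
(rarest = 1, ties take the more urgent rank); represented categories get
`5 + min(5, floor(5 × accession share / external share))`, pushing
already-over-collected categories to the bottom. Every acceptance check
rests on the anchor property, never on the stand-in's internal order.

Representativeness percentages are integer round-half-up shares of the
map's category count: the current share with accessions, and the
improvement available from collecting the gap categories. Round-half-up is
used for every printed percentage and count in the report tables; it is
the only rounding consistent with all published table values this package
reproduces, including the per-species 20% selection counts below.

## Predictive characterization

Among the priority ecogeographical gaps, sites likely to select for
drought and salinity tolerance are found by ecogeographical filtering
(the FIGS approach): compute the Lang aridity index

$$AI_L = \frac{\text{annual precipitation (mm)}}{\text{annual mean temperature (°C)}},$$

keep sites with $AI_L < 40$ (strictly; the index is undefined and the
record excluded when the mean temperature is not positive), and take per
species the top `round_half_up(0.2 × n)` records by topsoil salinity.
Two ambiguities were resolved as follows. The selection is
salinity-primary with aridity as tie-break (more arid first, then record
id): the workflow's results and the salinity-sorted layout of its
shortlist support salinity-only ordering after the aridity filter, while
the methods phrasing "lowest aridity and highest salinity" is honoured in
the tie-break. The 20% fraction is applied per species, which is the only
reading that reproduces all five published count pairs
(10→2, 103→21, 76→15, 26→5, 8→2; total 45).

## The synthetic landscape generator

`generate_raster_stack()` builds the study territory: a regular 30
arc-second lat/lon grid with a ≥1-cell nodata "sea" margin (so every stage
must handle nodata), and per component a partition into `true_k` Voronoi
patches around random seed points — spatially contiguous zones like a real
ELC map, cheap to generate. Every variable of a component takes its zone's
mean plus i.i.d. Gaussian cell noise; `noise_sd` tunes how hard the zones
are to recover. Zone mean profiles live in the contrast space of the
zones, orthonormalized under the realized zone sizes, so the first
`true_k − 1` informative variables of a component are mutually
(near-)uncorrelated; additional variables take random directions and may
correlate, as real environmental layers do. A small random mixing (sd
0.08) keeps the zone simplex off a degenerate geometry where the elbow
rule's 50% criterion sits exactly on its boundary and the chosen k would
be decided by floating-point noise. Planted redundant layers are linear
transforms of a partner plus just enough noise to hit a target Pearson r —
the pruning stage's ground truth. Three designated layers
(`annual_precipitation`, `annual_mean_temperature`, `topsoil_salinity`)
are affinely rescaled to realistic units (≈360–840 mm, ≈9–19 °C,
≈0–6 dS/m), which puts the Lang index around 19–88 so the $AI_L < 40$
filter genuinely splits the territory.

`sample_occurrences()` draws accessions and externals from land cells.
Categories listed as withheld never receive accessions (guaranteed
ecogeographical gaps) and each withheld category receives at least one
external record. A fraction of records get an injected twin under 1 km
away (`round_half_up(fraction × n)` twins, exactly); a fraction of
*external* records are degraded — coordinates truncated to one decimal and
locality removed — so the precision filter has real work. Degradation is
restricted to externals because the precision rule never removes
accessions, and degrading accessions would break the withheld-category
guarantee without testing anything.

What the generator does **not** emulate: realistic climate surfaces,
spatially autocorrelated noise within zones, island biogeography,
gazetteer errors, or taxonomic misidentification. Passing tests therefore
demonstrate the correctness of the algorithms under the stated data model,
not robustness to every failure mode of real occurrence data.

### Default study conditions

The default `pipeline_config()` analyses five synthetic congeneric species
whose record counts mirror the shape of a national CWR collection at desk
scale — one rare species (6 accessions, 30 externals) up to two
intensively recorded ones (60–80 accessions, 400–500 externals), each with
one or two withheld categories, 15% injected duplicates and 25% degraded
externals — on a 120×120-cell territory with three zones per component.
These sizes keep a full pipeline run under half a minute while leaving
every stage statistically non-trivial; the test suite uses 40×40-cell
territories for the property suites (20-seed category recovery, dedup and
spatial-gap oracles at several hundred to 1,500 records).

## Numerical choices and degenerate inputs

* Percent and count rounding: `round_half_up()` everywhere a table is
  printed.
* K-means: best of ≥10 restarts per k (50 on a monotonicity retry),
  `iter.max = 100`; fewer distinct cell profiles than centers (zero-noise
  landscapes) reuse the exact partition of the largest feasible k.
* Constant variables: dropped from clustering with a warning (error if a
  component has none left); importance 0 and ranked last in selection.
* Ties: importance ties break by variable name; selection-cut ties by rank;
  salinity ties by aridity then record id; priority-rank ties take the more
  urgent rank.
* Seeds: one master seed fans out to stage seeds via `derive_seed()`
  (a stable string-hash mix kept below 2^31), so a stage can be rerun
  alone and a rerun of the pipeline is byte-identical.
* Category 0 (unassigned/nodata) records are excluded from
  representativeness and ranking, with warnings.

## Known limitations

* The georeferencing-quality scorer and the within-band priority scoring
  are documented stand-ins; only their thresholded/banded behaviour is
  specified by the workflow they implement.
* ELC maps from real rasters depend on the actual layer stack; this
  package validates the machinery, not any particular territory's map.
* The spatial-gap and dedup scans are O(n²) per species; fine for national
  collections (thousands of records), not for continental GBIF dumps.
* Rasters are plain in-memory matrices with ESRI ASCII grid I/O; very
  large grids (beyond a few million cells) would need a tiled backend.
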