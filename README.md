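# elcgap

Ecogeographical gap analysis for crop-wild-relative (CWR) germplasm
collections.

Genebanks conserve CWR populations as *accessions*; floristic databases
report where the species actually occur (*external sources*). `elcgap`
answers the curator's question — *which reported populations should we
collect next, and which of those are most likely to carry drought and
salinity tolerance?* — with a reproducible pipeline:

1. **Occurrence QC** — parse MCPD-style records, remove low-precision
   external records (fewer than two declared decimals in both axes, no
   locality text, or UTM coarser than 1 km), score georeferencing quality
   on a 0–100 scale (keep > 80), and clear intraspecific spatial
   duplicates: records of one species and source class less than 1 km
   apart (great-circle) are one population.
2. **Variable selection** — per ecogeographical component (bioclimatic,
   edaphic, geophysic), rank variables by random-forest permutation
   importance (mean decrease in accuracy, real-vs-permuted contrast) and
   prune, within the top 15, pairs with Pearson |r| > 0.50 and p < 0.05,
   dropping the lower-ranked member.
3. **ELC map** — z-standardize the top 3 + 3 + 2 selected variables (plus
   latitude/longitude as geophysic variables) over all land cells,
   K-means each component with the elbow rule — the chosen k is the
   smallest n with (WSS(n) − WSS(n+1)) / WSS(n) < 0.5, capped at 8 — and
   combine the three label maps into Ecogeographical Land Characterization
   categories (one category per observed label triple).
4. **Gap analysis** — *spatial gaps*: external populations more than 1 km
   from every accession; *priority ecogeographical gaps*: external
   populations in ELC categories with no accession (collection ranks 1–4);
   representativeness = share of categories holding accessions.
5. **Predictive characterization** — among priority gaps, keep sites with
   Lang aridity index AI_L = annual precipitation (mm) / annual mean
   temperature (°C) < 40, and take per species the top
   `round_half_up(0.2 × n)` records by topsoil salinity.

A synthetic-landscape generator (`landscape_spec()`,
`generate_raster_stack()`, `sample_occurrences()`) produces raster stacks
and occurrence tables with known ground truth — Voronoi zone structure,
planted correlated variables, injected duplicates, degraded coordinates,
spatially biased accessions — so the whole pipeline is testable offline.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` for elbow curves and
ELC maps. Rasters are plain matrices read and written as ESRI ASCII grids.

## Worked example

```r
library(elcgap)
library(dplyr)

# a synthetic territory with known zone structure, and one species whose
# accessions cluster spatially (as real collecting missions do)
land <- generate_raster_stack(landscape_spec(seed = 7))
occ <- sample_occurrences(land$truth, 40, 300,
  withheld_categories = c(3L, 9L),
  dup_fraction = 0.15, degrade_fraction = 0.25,
  accession_cluster_sd = 0.2,
  species = "Synthetica exempli", seed = 71
)

rec <- qc_pipeline(parse_occurrences(occ))
qc_report(rec)
#>   source_class n_initial n_low_precision n_duplicates n_quality_gt
#> 1 accession           46               0            6           40
#> 2 external           345              86           32          227
```

86 degraded external records fail the precision filter and 32 + 6 spatial
duplicates are cleared; 227 external and 40 accession records pass the
quality threshold.

```r
passed <- filter(rec, qc_status == "retained", quality_pass)
sel <- select_variables(land$stack, passed, seed = 7)
fit <- build_elc_map(land$stack, sel$selection, seed = 7)
glance(fit$elc)
#>   n_categories n_land_cells
#> 1            7        13456

gaps <- analyze_gaps(list("Synthetica exempli" = fit$elc), passed)
gaps$report$gaps
#>   species            n_external n_spatial_gaps n_priority_gaps pct_priority
#> 1 Synthetica exempli        226            222              44           19
```

The fitted ELC map has 7 categories; 222 of 226 external populations are
spatial gaps and 44 (19%) sit in categories with no accession — the
priority ecogeographical gaps. The collection currently represents 4 of 7
categories (57%); collecting the gaps would add 3 more.

```r
priority <- filter(gaps$ranked[["Synthetica exempli"]], is_priority_gap)
pc <- predictive_characterization(land$stack, priority)
pc$counts
#>   species            n_arid n_selected
#> 1 Synthetica exempli     44          9
head(pc$report, 3)
#>   species            latitude longitude lang_index topsoil_salinity
#> 1 Synthetica exempli     40.4     -3.50         21              6.6
#> 2 Synthetica exempli     40.7     -3.49         20              2.9
#> 3 Synthetica exempli     40.9     -3.32         20              2.8
```

All 44 priority gaps lie on arid sites (AI_L < 40); the 20% rule selects
the 9 with the highest topsoil salinity as the predictive-characterization
shortlist — candidate collection sites for drought and salinity tolerance.

The full five-species study is one call:

```r
bundle <- run_pipeline(pipeline_config(seed = 42))
bundle$gap_table        # per-species spatial/priority gap counts
bundle$pc_table         # the drought/salinity shortlist
write_report_bundle(bundle, "reports")
```

See `vignettes/elcgap-methods.Rmd` for the models, assumptions, design
choices and limitations.

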