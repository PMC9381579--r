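# rpekit

Quantitative analysis tools for iPSC-derived retinal pigment epithelium
(RPE) disease-modelling studies, where monolayers from patients carrying
a splicing-factor mutation (e.g. *PRPF31*-linked retinitis pigmentosa)
are compared against control, asymptomatic-carrier, and
isogenic-corrected lines. The package covers the four analysis layers
such a study needs, each testable end to end on seeded synthetic data
with exact ground truth:

* **Morphometry** — ZO-1 (tight-junction) images are binarized (maximum
  filter, Gaussian blur, Otsu), partitioned into cells by Voronoi
  influence zones of the junction-bounded interiors, and measured per
  cell: area (pixel count), Crofton perimeter, convexity
  (convex-hull perimeter / perimeter), and geodesic diameter (longest
  within-cell shortest path under chamfer weights, exact against a
  Dijkstra oracle).
* **DEG cluster selection** — TPM floor (≥ 5 in one sample), |log2FC| ≥ 1
  with FDR < 0.05 per contrast, z-scores of group means of log2(TPM+1),
  Ward hierarchical clustering into K clusters, and a centroid-margin
  rule selecting clusters where the affected group separates from every
  control by ≥ δ.
* **Splice-event selection** — rMATS `*.MATS.JC.txt` dialect parser, the
  event filters (min count 2, FDR < 0.05, |ΔPSI| > 10%, min PSI 10%,
  optional host-gene TPM floor), coordinate-exact event identity across
  comparisons, mutation-specific set logic (A ∩ B) \ C, and event-type
  composition reports.
* **Assay arithmetic** — TER normalization ((raw − blank) × area,
  Ω·cm²), phagocytosis FITC/DAPI ratios (bound = total − quenched),
  western band ratios and folds, marker-positive fractions, ONL
  densities, ΔCt folds (2^−ΔΔCt), and Kruskal–Wallis / ANOVA group tests
  with Dunn / Tukey post-hocs.

Synthetic generators (`simulate_epithelium()`, `simulate_count_table()`,
`simulate_splice_tables()`, `simulate_assay_fixtures()`) are first-class,
seeded, and ship the ground truth needed to verify every stage.

## Worked example

Simulate an irregular monolayer, measure it, and summarize the
convexity distribution:

```r
library(rpekit)

spec <- epithelium_spec(n_cells = 150, jitter_sigma_px = 6, rng_seed = 42)
epi  <- simulate_epithelium(spec)
records <- measure_epithelium(epi$image)
head(records, 3)
#> # A tibble: 3 x 8
#>   cell_id area_px perimeter_px convexity geodesic_diameter_px ...
#> 1       1    1572         152.     0.984                 56.8
#> 2       2    2110         182.     0.972                 67.3
#> 3       3    2030         171.     0.992                 62.7

summarize_distribution(records, "convexity", group = "jitter6")
#> <shape_distribution> jitter6 | convexity: n = 107, median = 0.9863, IQR = 0.01039
```

107 interior cells survive edge exclusion; the median convexity near
0.99 says the cells are nearly convex, and the IQR is the spread
statistic that separates regular from irregular monolayers (a
jitter-free tessellation at the same seed gives a visibly smaller IQR).

Select mutation-specific genes from a synthetic table with a planted
affected-only pattern, then intersect splice events across comparisons:

```r
cspec <- count_table_spec(planted_sets = list(
  list(genes = 1:300, offsets = c(0, 0, 3, 0), label = "mutation_specific")),
  rng_seed = 42)
sim   <- simulate_count_table(cspec)
stats <- welch_de_stats(sim$tpm, sim$groups,
                        list(c("affected", "control"),
                             c("affected", "asymptomatic")))
sel <- select_mutation_specific_genes(sim$tpm, sim$groups, stats, "affected")
sel
#> <deg_selection> 4951 expressed, 300 DEGs, 297 selected genes
```

297 of the 300 planted genes land in the selected clusters (the planted
log2 offset of +3 in the affected group is far above the fold-change
threshold, and their z-profiles cluster away from every control).

```r
sspec <- splice_table_spec(planted_significant = list(
  affected_vs_control = list(events = 1:150, delta_psi = 0.4),
  affected_vs_asympto = list(events = 1:150, delta_psi = 0.4),
  asympto_vs_control  = list(events = 151:200, delta_psi = 0.4)),
  rng_seed = 42)
ssim <- simulate_splice_tables(sspec)
sig  <- lapply(ssim$events, significant_events)
res  <- intersect_mutation_specific(sig$affected_vs_control,
                                    sig$affected_vs_asympto,
                                    sig$asympto_vs_control)
res
#> <splice_intersection> 150 events on 86 unique genes
splice_composition(res)
#> 1 SE            63    42
#> 2 MXE           37    24.7
#> 3 RI            24    16
#> ...
```

The 150 events planted in both affected-line comparisons (and absent
from the carrier-vs-control comparison) are recovered exactly; the
composition table is the input for an event-type pie chart.

A one-command demo of all stages, with manifests and TSV/CSV outputs:

```r
demo_pipeline(seed = 7, out_dir = "demo_out")
```

or from a shell: `Rscript inst/scripts/pipeline.R demo --seed 7 --out demo_out`.

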