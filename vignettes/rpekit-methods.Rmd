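---
title: "Methods: epithelial morphometry and mutation-specific transcriptomic selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epithelial morphometry and mutation-specific transcriptomic selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpekit)
```

`rpekit` implements the quantitative analysis layer of a retinal pigment
epithelium (RPE) disease-modelling study design: iPSC-derived RPE
monolayers from patients carrying a splicing-factor (PRPF31) mutation are
compared against control, asymptomatic-carrier, and isogenic-corrected
lines by (i) cell-shape morphometry on tight-junction (ZO-1) images,
(ii) selection of mutation-specific differentially expressed gene (DEG)
clusters, (iii) selection and intersection of alternative-splicing events
from rMATS-format tables, and (iv) closed-form assay quantifications.
Every stage can be exercised on seeded synthetic data with exact ground
truth, which is how the package tests itself.

## Morphometry: from junction image to shape distributions

A junction-stained monolayer is a bright network of cell borders over
dark interiors. The pipeline is:

1. **Preprocessing** (`preprocess_junctions()`): grayscale maximum filter
   (disc radius 2 px), Gaussian blur (sigma 2 px), then Otsu
   thresholding. The max filter closes small gaps in the staining before
   binarization; both parameters are exposed because staining quality
   varies. A constant image is an error, never an empty mask.
2. **Partition** (`partition_cells()`): connected components of the
   inverted mask (4-connectivity by default) are the cell interiors;
   every junction pixel is then assigned to the chamfer-nearest interior
   — the geometric influence zones of the components, equivalent to a
   watershed of the distance transform seeded by the interiors. After
   this step label ownership is a total function on the frame: areas sum
   exactly to the pixel count, which the tests assert.
3. **Post-filtering** (`postfilter_labels()`): holes are filled, labels
   are dilated (1 px default) into unassigned pixels only, labels
   touching any border row/column are removed (edge cells are truncated
   by the field of view and would bias shape statistics), and labels
   under 50 px are dropped as segmentation debris.
4. **Measurement** (`measure_shapes()`): per cell,
   * *area* is the raw pixel count;
   * *perimeter* is the 4-direction Crofton estimate
     (pi/4 times the weighted count of foreground runs along rows,
     columns, and the two diagonal families, diagonal spacing
     1/sqrt(2)). On a digitized disc of radius 30 px this lands within
     3% of the true circumference (test-enforced); axis-aligned
     rectangles are the estimator's worst case (pi(2 + 2 sqrt(2))/16 of
     the true value, about 5% under);
   * *convex perimeter* is the perimeter of the convex hull of boundary
     pixel centers, and *convexity* their ratio — 1 for convex shapes,
     lower for irregular ones;
   * *geodesic diameter* is the largest within-cell shortest-path cost
     under chamfer weights (1 axial, sqrt(2) diagonal), computed by
     farthest-point propagation from every boundary pixel with
     eccentricity-bound pruning (after propagating from one source, any
     other source whose triangle-inequality upper bound cannot beat the
     current best is skipped — so convex cells need only a handful of
     propagations). A two-point alternating scheme started from the
     maximal inscribed disc was tried first and can stall in
     locally-farthest pairs even on convex raster cells; the boundary
     sweep does not, and it matches an all-pairs Dijkstra oracle on
     every shape we test — bars, L and U shapes, spirals, Voronoi
     cells. Exactness is defined against that oracle under identical
     weights, not against continuous geometry. A 1-px cell has diameter
     0 and undefined convexity and is flagged `excluded`.

`summarize_distribution()` bins one metric per group (median, IQR, CV
alongside), and `compare_groups()` runs a Kruskal–Wallis omnibus test on
per-cell values. Cells are pooled across images by default; per-image
averaging is a matter of passing per-image summaries instead.

### Numerical choices and caveats

* Chamfer (1, sqrt(2)) weights overestimate Euclidean length by up to
  ~8% depending on orientation. This bounds how well geodesic-diameter
  *ranks* can agree with continuous truth when cells are near-identical
  in size; with heterogeneous cell sizes the Spearman correlation against
  truth exceeds 0.95.
* Convexity of a digitized convex cell sits slightly below 1 (the hull
  of pixel centers is inset ~0.5 px relative to the Crofton perimeter);
  for cells with perimeter over ~80 px this bias stays within the 5%
  band the tests enforce.
* Influence-zone ties (a junction pixel equidistant from two interiors)
  resolve deterministically to the smaller label.

## Synthetic epithelium generator

`simulate_epithelium()` renders a Voronoi tessellation: seeds are placed
uniformly, relaxed by a configurable number of Lloyd (centroidal) steps,
then displaced by Gaussian jitter. Relaxation and jitter are separate
dials on purpose: relaxation sets how honeycomb-like the monolayer is,
jitter reintroduces the shape and size heterogeneity that distinguishes
dysfunctional monolayers. The junction band (3 px default) is drawn
bright over dark interiors, then blurred (sigma 1 px) and degraded with
Gaussian noise (sd 0.02 on a 0–1 scale) — modest values typical of
well-exposed confocal images. Exact truth accompanies every image: the
Voronoi polygons clipped to the frame minus the background margin, with
geometrically computed area, perimeter, hull perimeter, convexity, and
geodesic diameter (for a convex polygon the geodesic diameter is the
largest vertex-to-vertex distance).

Because Voronoi cells of any seed set are convex, *true* convexity is
always 1; jitter manifests in the *measured* distributions through cell
size and elongation: the convexity distribution widens (larger IQR) and
the geodesic-diameter distribution shifts, which the rank-based group
test detects. This is exactly how the tests probe spread recovery
(jitter 0 vs 8 px, 200 cells per group). What the generator does *not*
emulate: staining dropouts, intensity gradients, curved junctions,
multi-layered regions — so passing tests demonstrate correctness of the
measurement pipeline, not robustness to every real-world artifact.

Collisions (two seeds closer than twice the junction width after
jitter) trigger a resample of the displacement with a bounded retry
count, then an error.

## DEG selection

Inputs are a TPM table (genes x samples), a sample-to-group assignment,
and per-contrast statistics (log2 fold change, p, FDR) — the package
consumes differential-expression statistics rather than re-fitting a
count model, since the contribution here is the selection layer, not the
model fit. The chain (`select_mutation_specific_genes()`):

1. **Expression floor** (`tpm_filter()`): TPM >= 5 in at least one
   sample (inclusive), or at least one group mean — both readings occur
   in practice, so the mode is a config field (`tpm_mode`).
2. **DEG filter** (`deg_filter()`): |log2FC| >= 1 (fold change of 2,
   boundary inclusive) and FDR < 0.05 (strict; a `pval` column mode
   covers designs filtered on raw p at the same threshold).
3. **z-profiles** (`zscore_profiles()`): group means of log2(TPM+1)
   standardized per gene across groups with the *population* sd, so a
   two-group profile is exactly (-1, +1). The pseudo-count of 1
   stabilizes low-expression genes. Constant genes cannot be
   standardized and are dropped with a message.
4. **Clustering** (`cluster_genes()`): Ward linkage (`ward.D2`) on
   Euclidean distances between z-profiles, cut into exactly K clusters
   (K = 15 default, mirroring a four-group RPE design; 14 fits a
   three-group organoid design). Continuous profiles make merge ties a
   measure-zero event, so the partition is invariant to gene input
   order; residual ties resolve by `stats::hclust` index order.
5. **Selection** (`select_clusters()`): the by-eye step of picking
   heat-map clusters is formalized as a centroid-margin rule — a cluster
   is selected iff its centroid satisfies |z(affected) - z(g)| >= delta
   for *every* control group g (delta = 1 default). The selected gene
   list is monotone non-increasing in delta, which a test asserts. This
   rule is an explicit formalization, not a claim about how any
   particular published cluster set was hand-picked.

The synthetic generator (`simulate_count_table()`) plants
mutation-specific sets as per-group log2 offsets on negative-binomial
counts; TPM uses a unit gene-length convention (counts scaled to one
million per sample) because gene length cancels out of every downstream
filter. The default dispersion of 0.01 is the standard biological
coefficient of variation (~0.1) for genetically identical cultured
lines; with triplicates and the Welch + Benjamini–Hochberg stand-in
statistics this makes a planted (0, 0, +3, 0) pattern recoverable at the
>= 90% level the generator's truth labels promise, while null tables
select essentially nothing. With `dispersion = 0` counts are the rounded
model means, giving closed-form expectations for tests.

## Splice-event selection

`read_rmats()` parses the rMATS junction-count dialect (one file per
event type; header-name lookup, comma-joined per-replicate lists, `NA`
for missing PSI; the count columns are explicitly read as text so that
comma-separated lists are never misread as group-separated numbers).
Coordinates stay exactly as rMATS writes them (0-based starts, 1-based
ends); `event_keys()` builds the identity used across comparisons from
event type + chromosome + strand + the full coordinate tuple, with the
gene id as a tiebreak. Coordinate-exact matching is strict on purpose:
gene+type matching would merge distinct events on the same gene.

`significant_events()` applies, in conjunction: junction support
(inclusion + skipping reads >= 2 in at least one sample, inclusive), FDR
< 0.05 (strict), |inclusion-level difference| > 0.10 (strict, matching
"more than 10%"), and a minimum PSI of 0.10. "Minimum PSI" is ambiguous
in common usage, so the default keeps events where at least one group's
mean PSI reaches 10% (the event is actually included somewhere); the
alternative reading — both groups inside [0.1, 0.9] — is a config
switch. An optional TPM >= 5 floor on the host gene supports
organoid-style selections and errors if no expression table accompanies
it. Events with PSI missing in all replicates of a group are dropped
with a message.

`intersect_mutation_specific()` computes (A ∩ B) \ C on event keys —
events significant against both the control and the asymptomatic
carrier but not between carrier and control are specific to the
affected line. Two-set (plain intersection) and single-set modes cover
designs with fewer informative comparisons. `splice_composition()`
reports per-type counts/percentages and the unique host-gene count.

The synthetic generator shares one event catalogue across comparisons
(so set logic is meaningful) and draws binomial junction counts around
group PSIs, with a two-proportion test on summed counts standing in for
the rMATS likelihood (the pipeline only ever consumes the p/FDR
columns). The default junction depth of 500 reads per replicate is
deliberately deep: at that depth a 10% PSI fluctuation is more than
5 sd of counting noise, so the generator's planted/null truth flags
coincide exactly with the filter outcome — the contract its examples
state. Shallower depths are available and produce realistic borderline
events, at the cost of that exactness.

## Assay quantifications

All closed-form maps, vectorized, with an independent scalar
recomputation as the test oracle:

* TER: (raw − blank) × membrane area, in Ω·cm²; sub-blank wells stay
  negative but are flagged.
* Phagocytosis: internalized = quenched/DAPI; bound = (total −
  quenched)/DAPI, clamped at 0 with a warning when quenching exceeds
  total (quench variability, not an error). Before clamping,
  internalized + bound = total/DAPI exactly.
* Western: ratio = target/loading; fold = ratio / arithmetic mean ratio
  of the reference group (the arithmetic mean was chosen over the
  geometric; both appear in practice, the difference is second-order at
  these effect sizes).
* Marker fraction (100·n/nDAPI), region density (n/area).
* qPCR: ΔCt against the housekeeping gene; fold = 2^−(ΔCt − refΔCt),
  assuming perfect doubling per cycle (no efficiency correction, which
  the ΔCt method does not include).
* `group_test()`: Kruskal–Wallis with Dunn's rank post-hoc
  (Benjamini–Hochberg adjusted) or one-way ANOVA with Tukey's HSD,
  reporting mean ± SD per group.

## Pipeline and problem sizes

`run_pipeline()` drives the stages from one config; `demo_pipeline()`
runs everything on synthetic data. Stage seeds derive from the global
seed by hashing the stage name, so stages are independent but the whole
run is reproducible — two runs with the same seed are byte-identical,
including manifests (config hash, seed, row counts). The demo sizes —
a 512×512 image with 150 cells, 5,000 genes × 4 groups × 3 replicates,
2,000 splice events across 3 comparisons — are chosen as the smallest
sizes at which every selection step operates in its intended regime
(BH correction with a realistic null mass, clusters with hundreds of
genes, a composition with all five event types) while a full demo stays
comfortably under a few minutes on one CPU.

## Known limitations

* True Voronoi cells are convex, so the generator cannot produce
  genuinely concave ground-truth cells; measured concavity arises only
  from noise and discretization. Concave-cell correctness is covered by
  the structured-shape tests (U, L, spiral) instead.
* The geodesic propagation scheme is a heuristic with a multi-start
  refinement; it matches the exact oracle on every tested shape, but a
  pathological shape could in principle defeat it. The oracle-equality
  test, not a proof, is the guarantee.
* The Welch-test stand-in is less powerful than a count-model fit;
  planted-recovery rates quoted here are specific to the generator's
  dispersion and replicate defaults.
* Statistical behavior is validated on synthetic data only; nothing here
  validates segmentation against real ZO-1 images.
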