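---
title: "Methods: spatial mapping of tumor microenvironments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial mapping of tumor microenvironments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmemap)
```

`tmemap` implements a complete neighborhood/region analysis of tumor tissue
starting from segmented cell-object tables, together with a synthetic tissue
generator that provides ground truth for every stage. This vignette explains
the model behind each stage, the parameters that matter, the numerical
conventions, and what the synthetic benchmark does and does not show about
real data.

## Cell tables and gating

The pipeline's input is the standard histocytometry export: one CSV row per
segmented cell with sample ID, centroid position (µm), per-channel MFIs, and
optionally volume (µm³) and sphericity. `read_cell_table()` accepts a column
mapping so differently named exports share one reader; extra columns pass
through untouched. Validation enforces finite positions, nonnegative MFIs,
and sphericity in [0, 1].

Phenotypes are assigned by `apply_gates()` from a tree of per-channel
threshold conjunctions. The original workflow gates interactively in
flow-cytometry software; we replace this with absolute cutoffs in a YAML
config for reproducibility, at the cost of fidelity to any particular
hand-drawn gate. The shipped `default_panel()` encodes the usual subset
hierarchy (CD3/CD8 → TCF1/PD1 stratification of CD8 T cells; CD3⁻ CD11c⁺
MHCII⁺ DCs split by CD103/SIRPα; CD11c⁻ macrophage subsets by CD206 and
MHCII) with all cutoffs at MFI 40, which sits roughly 3 SD from both modes
of the generator's bimodal intensity model (positives N(100, 12), negatives
N(5, 3), truncated at 0). On real data the cutoffs must be recalibrated per
experiment; the tree structure, not the numbers, is the shipped content.
Cells are routed to the first matching child at each level, so overlapping
predicates resolve deterministically in document order; unresolved cells are
labelled `other`, making the labels a partition.

## Raster neighborhoods

`raster_neighborhoods()` lays a square grid of window centers (spacing `s`,
default equal to the radius) anchored at the cell bounding-box corner of
each sample, and counts cells of each phenotype within a **closed** ball of
radius `r` (default 50 µm, a scale that spans a few cell diameters and
matches the niche sizes of interest). Landmarks are counted the same way —
tumor-marker spots as points, vessels as point-to-segment distances — so the
composition space includes non-cellular anatomy. Conventions worth stating:

- Closed-ball inclusion: a cell at exactly `r` belongs to the window. This
  is an arbitrary but deterministic tie-break.
- `s = r` windows overlap (a cell can contribute to several windows);
  `s = 2r` makes windows disjoint. The raster step is not a scientific
  parameter so long as it is fixed across samples; we default to `s = r`.
- Windows containing neither cells nor landmarks are dropped: background
  space would otherwise dominate region clustering. Windows that contain
  only landmarks (e.g. deep tumor nest with only marker spots) are kept —
  they are tissue, not background.
- Counting is by cell centroid, not object volume overlap.

Counts can be re-expressed per window area (`normalize_neighborhoods`,
"density") or as composition fractions; both transforms retain enough
information to be inverted exactly, which the tests exploit.

## Spatial correlation

`correlation_matrix()` computes Pearson correlation between per-window
counts of every pair of populations, pooled across all samples (per-group
splitting is available). Significance uses the classical Student-t
transform of the correlation, *t = r√((n−2)/(1−r²))* with *n−2* degrees of
freedom, two-sided. No multiple-testing correction is applied by default —
the matrix itself is the reported object — but Benjamini–Hochberg is
available via `p_adjust = "BH"`. Zero-variance columns yield `NA` rather
than a defined correlation. Intensity context (e.g. PD-L1 bands) can be
added as pseudo-labels: `add_channel_bands()` discretizes the per-window
mean MFI at configurable quantiles (default 0.5/0.9, i.e.
intermediate/high), since no published cutoffs exist for these bands.

## Tumor border and distances

The tumor nest is defined on the neighborhood grid: windows whose
tumor-spot count reaches a threshold θ form a mask; the largest 4-connected
component is kept (satellite blobs are logged and discarded), single-window
holes are filled, and the border is the contour of grid-cell edges between
mask and complement. A grid contour was chosen over a concave hull of the
spots because it inherits the resolution of the neighborhood analysis and
is robust to isolated spots. θ is data-dependent; a useful default on dense
spot fields is the *half-maximum* rule — half the median count of
deep-interior windows — which places the contour where window–disk overlap
is 50%, i.e. on the true boundary. With grid spacing `s` the contour is
accurate to about one grid step, which is the resolution claim the tests
verify against an analytic disk.

`signed_distance_to_border()` returns the exact Euclidean distance to the
nearest contour edge, signed positive inside and negative outside (the
convention under which infiltration depth is positive). The sign comes from
mask membership of the grid cell containing the query point, so it is
consistent with the contour by construction. `nearest_distance()` gives
exact point-to-segment distances to vessel centrelines, and
`summarize_distances()` reports per-phenotype quantiles plus the fraction
within 25 µm — the conventional "highly proximal" band for perivascular
positioning.

## Region clustering

Windows are clustered on their standardized composition vectors (cell
counts *and* landmark counts — vessels belong in the composition space
because vessel-rich regions are biologically meaningful). The clustering is
a batch self-organizing map (`som_fit`): nodes on a rectangular grid
(default 10×10, large enough that distinct compositions do not compete for
nodes at cohort scale), Gaussian neighborhood kernel whose width shrinks
linearly from a third of the grid diagonal to 0.5 node spacings, codebook
initialized from seeded data-row draws. Batch updates make each sweep a
closed-form weighted mean, so 50 sweeps (default) reach a stable map where
an online SOM would need hundreds of epochs; training is deterministic
given the seed.

The published workflow merges SOM clusters into named regions by hand. We
replace manual concatenation with Ward-linkage hierarchical clustering of
the codebook vectors cut at a user-chosen K, and the manual annotation with
a rule: a region is `t_cell_rich` when the **mean** fold change of the
infiltrating (PD1⁺ resource and effector) CD8 subsets is at least τ_T
(default 2), `tumor` when the tumor-spot fold change reaches τ_C (default
2) without that CD8 enrichment, and `other` otherwise. The mean — not the
sum — is compared against the threshold so that the no-enrichment baseline
is 1 regardless of how many subsets are listed; a summed statistic would
make the baseline grow with the subset count and misclassify unenriched
regions. Fold change here is the region's mean count per window divided by
the overall mean count per window, the same statistic as the region
heatmap, and is invariant to duplicating windows.

`embed_neighborhoods()` provides a seeded, single-threaded UMAP of the same
feature space for visualization; it plays no role in any quantitative
output.

## Tumor volume and the region-ratio biomarker

Caliper volume is ½·L·W² (mm³); fold change is V(end)/V(initiation), the
simplest reading of "after the initiation of therapy", with the baseline
timepoint configurable. The spatial biomarker is the per-sample prevalence
ratio ρ = Σ prevalence(t_cell_rich) / Σ prevalence(tumor). Prevalence
rather than absolute region area is used; the two differ only by a
per-sample constant, which cancels in the correlation with outcome. Samples
with zero tumor-region prevalence produce ρ = ∞; they are flagged and
excluded from the cohort correlation (the alternative — imputing a large
finite value — would manufacture leverage). `outcome_association()` reports
Pearson r with the t-transform p-value; a constant biomarker yields `NA`.

## The synthetic tissue generator

The generator emulates the spatial structure the analysis assumes, in 2D
(sections): a disk-shaped tumor nest of marker spots, a CD206⁺ macrophage
capsule in an annulus outside the nest, straight vessel segments placed
outside the deep nest, and phenotype populations placed by rule:
uniform, inside-nest, capsule-ring, near-boundary (Gaussian radial offset
about the nest edge), and perivascular. Intensities follow the bimodal
model above, so default gating recovers the true labels exactly — by
design: gating errors would otherwise confound every downstream test.

Two generator choices deserve explanation:

- **Perivascular displacement.** A cell is anchored at a uniform point
  along a random vessel (probability proportional to length) and displaced
  along the local vessel *normal* by the radial magnitude of an isotropic
  2D Gaussian with SD σ_v — a Rayleigh(σ_v) draw. Because the displacement
  is normal to the segment, the anchor is the nearest point of that vessel
  and the cell's distance to it is *exactly* Rayleigh distributed, giving
  closed-form oracles (e.g. the fraction within 25 µm at σ_v = 10 µm is
  1 − exp(−3.125) ≈ 0.956). An unconstrained isotropic displacement would
  instead make the point-to-segment distance half-normal, because the
  tangential component is absorbed by the segment.
- **Vessel clearance.** Vessels are placed with a minimum pairwise
  clearance of 60 µm so that a perivascular cell's nearest vessel is its
  own anchor vessel; without clearance, crossing vessels measurably distort
  the distance law. Sixty micrometres is ≥ 4σ_v for the σ values used, so
  contamination of the law is negligible.

The cohort generator draws an infiltration parameter φ ∈ [0, 1] per sample
(default: evenly spaced over [0.05, 0.95], emulating a cohort spanning
untreated through combination-treated animals). φ scales the perivascular
DC/activated-Mf/T-cell pools, and moves the effector CD8 placement mixture
toward the nest interior (resource CD8 cells stay perivascular/boundary —
the planted spatial contrast between the two subsets). Outcome is linked as
fold change = a − b·φ + N(0, σ_fc), defaults a = 3, b = 2, σ_fc = 0.25,
truncated below at 0.05; caliper length/width pairs are back-computed (at a
fixed 1.4 aspect ratio) so ½·L·W² reproduces the linked fold change
exactly. Tissue scale defaults — 1000×1000 µm domain, 300 µm nest, 100 µm
capsule, 8 vessels of ~250 µm, ~900–1500 cells per sample — are desk-scale
study conditions: large enough for several hundred occupied windows per
sample and stable region structure across a 20-sample cohort, small enough
that a full cohort analysis runs in about a second.

For region-recovery validation independent of tissue geometry,
`generate_archetypes()` plants k composition archetypes directly in feature
space: archetype j elevates its own block of 3 features, pairwise mean
separation is exactly `separation` (default 6 within-class SDs — distinct
tissue regions differ strongly in composition), and isotropic Gaussian
noise is added.

### What the synthetic benchmark does not show

The generator produces convex nests, straight non-branching vessels,
cleanly bimodal intensities and independent cell placements. Real tumors
have irregular, multi-lobed nests, branched vasculature, spectral spillover
and segmentation errors, cell–cell exclusion and density gradients.
Passing the synthetic suite therefore demonstrates correctness of the
*machinery* (counting, geometry, statistics, clustering, linkage of
biomarker to outcome under a known model) — not that the default thresholds
or K will be right for any particular real dataset. Those remain
per-experiment choices.

## Numerical and degenerate-input conventions

- All RNG is seeded per call; the end-to-end pipeline is byte-identical
  across repeat runs under one seed.
- SOM best-matching-unit ties resolve to the lowest node index; gating ties
  resolve in document order; correlations of zero-variance columns are
  `NA`; p = 0 at |r| = 1.
- `train_regions()` errors when K exceeds the number of occupied nodes;
  empty landmark sets and unlabeled tables error early with the offending
  name; a border threshold that empties the mask suggests lowering θ.
- Problem sizes used in the shipped tests: windows up to ~7,500 per cohort,
  archetype recovery at 500 windows × 50 seeds, biomarker power at 20
  samples × 50 seeds linked plus 50 null seeds, perivascular geometry at
  n = 2,000 cells.

## Session info

```{r}
sessionInfo()
```
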