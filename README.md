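# tmemap

Quantitative spatial mapping of tumor microenvironments (TMEs) from
multiplexed-imaging cell tables.

Multi-parameter confocal or cyclic-staining microscopy of tumors is typically
reduced, via cell segmentation, to a table of cell objects: position, mean
fluorescence intensity (MFI) per channel, volume and sphericity. `tmemap`
takes the analysis from that point: it gates cell objects into immune
phenotypes, scans fixed-radius spatial neighborhoods across the tissue,
quantifies cell–cell colocalization, delineates the tumor nest and measures
signed infiltration distances and nearest-vessel distances, clusters
neighborhoods into tissue regions with a self-organizing map (SOM), and
derives a per-sample *region ratio* — T-cell-rich over tumor-region
prevalence — as a spatial biomarker of response to immunotherapy. A
synthetic tumor-tissue generator with full ground truth (tumor nest,
macrophage capsule, vessels, perivascular immune niches, graded T-cell
infiltration) backs every step with testable oracles.

Intended users: imaging scientists and computational biologists analyzing
segmented multiplexed imaging of tumors (histocytometry-style exports), and
methodologists who need a reproducible, fully synthetic benchmark for
neighborhood/region pipelines.

## The method in brief

- **Gating.** A tree of per-channel threshold predicates assigns each cell
  one phenotype (DC1, DC2, CD206⁺ Mf, MHCII± Mf, TCF1⁺PD1⁺ *resource* CD8,
  TCF1⁻PD1⁺ *effector* CD8, other CD8, CD4 T, other), first-match,
  deterministic.
- **Neighborhoods.** Windows of radius *r* = 50 µm raster-scanned at spacing
  *s* over each sample; each window holds counts of every phenotype and
  landmark kind (tumor-marker spots, vessels). Closed-ball inclusion.
- **Spatial correlation.** Pearson *r* between per-window counts of each
  population pair, pooled across samples; two-sided significance from the
  Student-*t* transform *t = r √((n−2)/(1−r²))* on *n−2* df.
- **Border and distances.** The tumor nest is the thresholded, largest
  connected component of per-window tumor-spot counts; its grid contour is
  the border. Distances are signed (positive inside, negative outside).
  Nearest-vessel distances are exact point-to-segment distances.
- **Regions.** Windows are clustered by a seeded batch SOM; nodes are merged
  to *K* regions by Ward linkage on codebook vectors; regions are classified
  `t_cell_rich` / `tumor` / `other` by fold-change rules, visualized by a
  region × population fold-change heatmap, per-sample prevalence, and a
  UMAP embedding.
- **Biomarker.** Caliper tumor volume ½·L·W², fold change V(t₁)/V(t₀), and
  the per-sample region ratio ρ = Σ prevalence(t_cell_rich) / Σ
  prevalence(tumor), correlated with fold change across the cohort.

## Worked example

Simulate a 20-sample cohort in which an infiltration parameter φ drives both
the size of the perivascular immune compartment and the tumor-volume fold
change, then run the full pipeline:

```r
library(tmemap)

res <- run_pipeline(cohort_spec(seed = 1))
res$summary
#> <region_summary> 6 regions, 20 samples
#> classes: R1=other, R2=other, R3=tumor, R4=other, R5=t_cell_rich, R6=t_cell_rich
#>      DC1  DC2 CD206_Mf MHCII+_Mf MHCII-_Mf CD8_TCF1+PD1+ CD8_TCF1-PD1+ ...
#> R2 10.96 3.49     1.79      3.18      0.39          2.00          1.58
#> R3  0.10 0.21     0.06      0.20      3.39          0.37          1.20
#> R5  2.62 5.17     1.86      5.40      1.42          4.59          3.42
#> ...
```

Region R3 reads as the tumor nest (tumor-spot fold change 3.3, non-activated
MHCII⁻ macrophages 3.4, T-cell depleted); R5 is the perivascular immune
niche (vessels 3.6, DC2 5.2, activated Mf 5.4, resource CD8 4.6); R2 is a
DC1-skewed vessel-associated region. The biomarker report:

```r
head(res$report$per_sample[, c("sample_id", "sum_t", "sum_tumor", "ratio",
                               "fold_change")], 4)
#>   sample_id  sum_t sum_tumor ratio fold_change
#> 1 s01       0.0811     0.238 0.341        2.74
#> 2 s02       0.0885     0.224 0.395        2.85
#> 3 s03       0.101      0.226 0.446        2.50
#> 4 s04       0.101      0.214 0.470        3.01

res$report$association
#> Pearson r = -0.890, p = 1.47e-07, n = 20
```

Samples with a higher ratio of infiltrated to excluded regions shrink more
(smaller fold change): the planted negative association is recovered.

Individual stages are available as plain functions —
`read_cell_table()` / `apply_gates()` / `raster_neighborhoods()` /
`correlation_matrix()` / `fit_border()` / `signed_distance_to_border()` /
`nearest_distance()` / `train_regions()` / `region_summary()` /
`region_ratio()` — see the package help and the methods vignette
(`vignettes/tmemap-methods.Rmd`).

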