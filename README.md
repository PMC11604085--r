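# spatialTME

Spatial tumour micro-environment analysis for imaging mass cytometry
(IMC) in R.

IMC images tissue with ~35 metal-tagged antibodies at ~1 µm resolution;
after cell segmentation, each region of interest (ROI) becomes a marked
spatial point pattern: cell centroids with per-marker mean intensities.
spatialTME implements the analysis chain used to compare tumour cohorts
— for example static versus growing schwannomas, where the clinically
standard cut-off classifies a tumour as *growing* at ≥ 20% volume
change per year — from such segmented cell tables:

* **Quantification** — per-marker normalisation to the cohort-wide
  99.9th percentile (clipped to [0, 1]), cell densities per mm², and
  normality-gated statistics (Shapiro–Wilk, then Pearson/t-test or
  Spearman/Mann–Whitney, two-tailed; two-way ANOVA for factorial
  designs; Benjamini–Hochberg FDR control).
* **Phenotyping** — kNN expression graph + Leiden clustering, with
  cluster annotation driven by declarative marker-signature rules
  (e.g. alternatively activated TAMs: CD16^high CX3CR1^high CD163+
  CD11b+ CD56−), hierarchical and granular rule tables, and
  sub-clustering of proliferative cells.
* **Cell neighbourhoods** — per-ROI Delaunay graphs pruned at the 99th
  percentile of edge lengths; l = 3-step neighbourhoods summarised by
  composition/shape/distribution/proximity features; Gaussian-mixture
  clustering with the number of clusters selected by Fowlkes–Mallows
  stability; enrichment annotation (FC ≥ 1) into tumour-, vasculature-
  and immune-enriched, proliferative or not; observed/expected
  neighbourhood proximity against a permutation null.
* **Spatial association** — quadrat correlation matrices (100 µm
  quadrats, BH-gated), border-corrected cross-pair correlation
  functions

  g(r) = |W| / (n_A·n_B) · Σ_a #{b : d(a,b) ∈ [r, r+dr)} / |annulus(a) ∩ W|

  over r = 0–300 µm with bootstrap 95% CIs and a positive/negative
  call at g(r = 20 µm), topographical correlation maps, and
  significance-gated adjacency cell networks with % connections.
* **Synthetic cohorts** — a simulator of multi-ROI marked point
  patterns (Poisson / Thomas-cluster / linked processes, lognormal
  expression noise, planted density–growth slopes, planted
  neighbourhood mosaics) with full ground truth, so every stage is
  testable offline.

## Worked example

Simulate a nine-case cohort (four static, five growing; here two
600 × 600 µm ROIs per case for speed), phenotype it, and test whether
alternatively activated TAM density tracks growth rate:

```r
library(spatialTME)

sc    <- default_scenario(seed = 42, rois_per_case = 2,
                          roi_width_um = 600, roi_height_um = 600)
sim   <- simulate_cohort(sc)
sim$cells
#> <cell_table> 5616 cells, 18 ROIs, 9 cases, 35 markers

cells <- normalize_expression(sim$cells)
cells <- phenotype_cells(cells, k_neighbours = 10, seed = 42)

dens  <- cell_density(cells, sim$geometry, "case_population")
v     <- with(dens[dens$label == "AltActTAM", ],
              setNames(density_per_mm2, case_id))
correlate_with_growth(v, sim$metadata)
#> pearson correlation: r = 0.831, p = 0.005534 (n = 9)
#> linear fit: y = 103.4 + 0.5728 x; normality p (x, y) = 0.299, 0.138
```

Both variables pass the Shapiro–Wilk gate, so the Pearson branch runs:
TAM density rises by ~0.57 cells/mm² per %/yr of growth (the scenario
plants a slope of 0.5; the cohort-level estimate recovers it within
noise) and the correlation is significant at n = 9 cases.

Spatial association between TAMs and T cells in one ROI:

```r
roi <- subset(as.data.frame(cells), roi_id == "SIM01_roi1")
g   <- build_spatial_graph(roi, roi_id = "SIM01_roi1")
g
#> <spatial_graph> SIM01_roi1: 350 cells, 1020 edges (pruned at 179.9 um)

bootstrap_pcf(subset(roi, population_label == "AltActTAM"),
              subset(roi, population_label == "TEM"),
              window = c(600, 600), n_boot = 200, seed = 42,
              sender_name = "AltActTAM", receiver_name = "TEM")
#> <crosspcf> AltActTAM -> TEM: g(r=20) = 43.425 [15.890, 74.424], call = positive
```

The simulator places T cells at Gaussian displacements (σ = 10 µm)
from TAMs, and the cross-PCF calls that attraction positive: g at the
20 µm bin is far above 1 with the whole confidence band above 1.

The same stages run end-to-end from one seeded YAML/R configuration via
`run_pipeline()`, which writes densities, growth correlations,
neighbourhood models, proximity matrices and adjacency networks as CSV
and is byte-for-byte reproducible for a fixed config and seed.

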