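# smlmtools

Quantitative analysis of 2D single-molecule localization microscopy
(SMLM) data in R.

SMLM techniques (dSTORM, PALM) reconstruct structure below the
diffraction limit from the coordinates of individually detected
fluorophores. The raw data are not images but *localization tables* —
one row per detection, carrying at minimum the x/y position and the
localization precision σ (the standard deviation of the position
estimate, typically 5–30 nm). Conventional image analysis does not apply
directly to such point data. `smlmtools` is for microscopists and image
analysts who need to turn localization tables into numbers: cluster
counts, sizes and shapes of nanoscale assemblies (DNA-repair foci,
nuclear pores, adhesions, virus particles), and averaged models of
structures imaged many times over.

## What it does

- **Import / ROI handling** — read ThunderSTORM-style or generic
  delimited localization tables (`read_locs`), filter them
  (`filter_locs`), and split a field of view into rectangular regions of
  interest with half-open membership, one table per ROI (`split_rois`).
- **Rendering** — per-localization Gaussian reconstruction where each
  detection contributes a 2D Gaussian with σ equal to its precision
  (`render_gaussian`); count-normalized kernel density estimation in
  localizations/µm², so that Σ pixels × pixel area = N and density
  thresholds are physically meaningful (`render_kde`); an extended
  scatter plot sized by precision (`scatter_export`); multi-channel RGB
  composites (`composite_channels`) and calibrated float TIFF output
  (`write_image`).
- **Cluster identification** — three segmentation routes returning
  per-localization labels (0 = noise):
  - `cluster_kde`: threshold the KDE image at an absolute density,
    label 8-connected components;
  - `cluster_dbscan`: classic DBSCAN (core point ⇔ ≥ `min_pts`
    neighbours within `eps`, counting itself);
  - `cluster_voronoi`: select localizations whose Voronoi tile area is
    below 2× the median tile area, group by Delaunay adjacency.
- **Cluster quantification** (`cluster_features`) — per cluster: count,
  centroid, mean precision, principal-axis standard deviations from the
  coordinate covariance, orientation, elongation = sd_major/sd_minor,
  size as FWHM = 2√(2 ln 2)·√(sd_major·sd_minor), convex-hull area, and
  mask area for image-based segmentations.
- **Benchmarking** (`make_s2_testset`, `score_clustering`) — a synthetic
  ground-truthed benchmark (six isolated Gaussian clusters of 50
  localizations, one 100-localization component of two overlapping
  clusters, 300 uniform noise points) and four performance parameters:
  true clusters detected (fusions counted once), false clusters, % of
  noise clustered, % of signal clustered.
- **Template-free particle averaging** (`compute_alignment`,
  `average_particles`) — align many copies of a structure by centre of
  mass and covariance major axis, orient the heavier side left, pool and
  render; recorded-motion recovery is exact by construction.
- **Command line** — `exec/smlm` exposes the workflow as subcommands
  (`simulate`, `split`, `render`, `cluster`, `features`, `score`,
  `average`) with JSON run logs and byte-reproducible outputs; see
  `?smlm_main`.

## Worked example

```r
library(smlmtools)

set <- make_s2_testset(s2_config(seed = 1))   # 700 localizations + truth
lab <- cluster_dbscan(set$locs, eps = 50, min_pts = 5)
lab
#> <cluster_labeling:dbscan> 700 localizations, 7 cluster(s), 292 noise

score_clustering(lab, set$truth)
#> <performance_report> 7 true cluster(s) detected, 0 false; 2.7% of noise and 100.0% of signal clustered

f <- cluster_features(set$locs, lab)
f[1:3, c("cluster_id", "n_localizations", "fwhm", "hull_area", "elongation")]
#>   cluster_id n_localizations  fwhm hull_area elongation
#> 1          1             100 74.64     15761      1.629
#> 2          2              54 60.95      9777      1.184
#> 3          3              53 55.48      8406      1.232
```

All 7 ground-truth components are recovered (the two overlapping
clusters fuse into the 100-localization cluster 1, counted once), no
noise-only cluster is formed, and the cluster sizes (FWHM ≈ 2.355 ×
geometric-mean spread of a 25 nm cluster broadened by localization
noise) come out around 55–75 nm.

The same pipeline from the shell:

```sh
exec/smlm simulate s2 --seed 1 --out run/
exec/smlm cluster dbscan --eps 50 --min-pts 5 --locs run/locs.csv --out run/labels.csv
exec/smlm score --labels run/labels.csv --truth run/truth.csv --out run/report.csv
```

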