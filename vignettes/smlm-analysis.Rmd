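---
title: "Quantitative SMLM analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative SMLM analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmtools)
```

Single-molecule localization microscopy produces point data: each
detected fluorophore contributes a coordinate pair $(x_k, y_k)$ and a
localization precision $\sigma_k$, the standard deviation of the
position estimate. This vignette describes the models implemented in
`smlmtools`, the parameters that matter, and the choices made where the
methodology leaves freedom. Everything shown here is computed by the
package at build time.

## Data model and conventions

A `loc_table` holds one row per localization: `x`, `y`, `precision`
(all nm, precision strictly positive), `channel` (≥ 1), optional
`frame` and `photons`, and a stable `id` preserved by all filters and
splits. Malformed rows in imported files (non-numeric fields,
non-positive precision) are dropped with a reported count rather than
aborting, because real localization exports routinely contain such
rows.

Two half-open conventions remove boundary ambiguity throughout:

* ROI membership is $x_{\min} \le x < x_{\max}$ (and likewise in y), so
  abutting rectangles partition the plane with no double counting.
* Rendering pixel $(i, j)$ covers
  $[x_0 + i\,s,\; x_0 + (i{+}1)\,s) \times [y_0 + j\,s,\; y_0 + (j{+}1)\,s)$
  for pixel size $s$, with $i$ the x index. Pixel grids are stored as
  matrices with rows indexing y (row 1 = lowest y bin).

## Rendering

**Gaussian rendering** places an isotropic bivariate Gaussian of
standard deviation $\sigma_k$ at each localization. Kernels are
evaluated at pixel centres and multiplied by the pixel area (midpoint
rule), not integrated per pixel; at the default 5 nm pixels and
$\sigma \ge 5$ nm the quadrature error is far below the kernel
truncation error. Each kernel is cut off beyond $4\sigma$, losing
$e^{-8} \approx 3.4\times10^{-4}$ of its mass — the bound behind the
$10^{-3}$ mass-conservation tolerance below. Intensity therefore mixes
density with precision, which is why this classic visualization is not
quantitative.

**KDE rendering** uses one global bandwidth $h$ and expresses pixel
values in localizations/µm², normalized so the density integrates to
the number of rendered localizations $N$:

$$\rho(p) \;=\; 10^{6} \sum_{k=1}^{N} \frac{1}{2\pi h^2}
  \exp\!\left(-\frac{\lVert p - p_k \rVert^2}{2 h^2}\right)
  \quad [\mathrm{loc}/\mu m^2].$$

Count normalization is the property that makes thresholding
transferable: a threshold of, say, 1000 loc/µm² means the same thing in
every field of view. For any table rendered with a margin of at least
$5h$ on all sides, $|\,\Sigma\,\rho \cdot A_{px} - N\,|/N < 10^{-3}$;
no renormalization is applied for mass lost off-field, so the guarantee
is stated only with that margin.

The default bandwidth (`bandwidth = "auto"`) is the mean localization
precision of the rendered table. This ties the degree of smoothing to
the measurement uncertainty while keeping the density units exact; any
fixed bandwidth may be supplied instead. The default pixel size of 5 nm
oversamples the 10–20 nm resolution of good dSTORM data at least
twofold.

Numerical notes: kernel patches are accumulated point by point in row
order, so rendering is linear in the table up to floating-point
summation order (verified to $10^{-12}$ relative); coordinates are
reduced to the grid origin before any pixel arithmetic, so equal shifts
of data and origin that are exact in floating point reproduce the image
bit for bit.

## Cluster identification

Three algorithms return the same structure — one integer label per
localization, 0 for noise, clusters numbered 1..K by descending member
count — plus provenance (algorithm and parameters), so downstream
feature extraction and scoring are algorithm-agnostic.

**Binary-KDE segmentation** (`cluster_kde`) thresholds the KDE image at
an absolute density, labels 8-connected foreground components, and
assigns each localization the label of its containing pixel.
Components with fewer than `min_size` member localizations (default 5)
are relabelled noise; this is what suppresses the spurious peaks that
single isolated localizations produce (a lone kernel with $h = 10$ nm
peaks at $\approx 1600$ loc/µm², well above plausible thresholds, but
contributes only one member). There is no universal default threshold:
it is a physical density the user chooses between the background and
cluster-peak densities of their data.

**DBSCAN** (`cluster_dbscan`) is the classic algorithm on 2D Euclidean
distance: a core point has at least `min_pts` neighbours within `eps`
(counting itself); clusters are density-connected sets; everything
unreachable is noise. Defaults are `eps` = 50 nm — about twice a
typical dSTORM precision — and `min_pts` = 5. Determinism is pinned
down explicitly: seeds are taken in ascending row order, expansion is
breadth-first, and a border point reachable from several clusters joins
the cluster whose lowest-row-id core point comes first. Neighbour
search uses an `eps`-sized grid, so behaviour is identical to the
brute-force definition (the test suite asserts equality with an
independent $O(n^2)$ implementation on 100 random instances).

**Voronoi tile-area thresholding** (`cluster_voronoi`) computes the
Voronoi tessellation of all localizations and selects those whose tile
area is below `threshold_factor` (default 2) times the **median** tile
area; unbounded border tiles are excluded from the median and never
selected. Selected localizations are grouped into clusters by Delaunay
adjacency (tiles sharing an edge), and groups below `min_size` become
noise. Tiles are built by clipping a bounding rectangle with
perpendicular-bisector half-planes, visited nearest-first with early
termination once no remaining bisector can cut the tile. Because
bounded sliver tiles near the data hull can extend far beyond the data,
the clipping box is enlarged (×100, twice) and the tile re-clipped
whenever it still touches the box; a tile that touches the box at every
scale is declared unbounded. Tile areas are exact polygon (shoelace)
areas; edges shorter than $10^{-9}$ of the data span are treated as
degenerate, which also removes the zero-length edges produced by
cocircular configurations such as regular grids. Exactly duplicated
coordinates have no tessellation and are rejected; fewer than three or
collinear points likewise.

**Scoring against ground truth** (`score_clustering`) implements four
benchmark parameters: ground-truth clusters detected, false clusters,
and the percentages of noise and of signal localizations assigned to
any cluster. The matching rule — not fixed by the benchmark definition
— is majority overlap: a truth cluster is detected iff at least 50% of
its members share one detected non-noise label; truth clusters matched
to the same detected label (fusions) count once; a detected cluster is
false iff fewer than half its members are signal. The 50% rule is the
simplest symmetric choice that reproduces the fused-cluster convention.

## Cluster features

Features derive from the member localizations directly (not from a
rendered image), so they are independent of pixelation: the centroid
and mean precision; principal-axis standard deviations from the
eigen-decomposition of the $2\times2$ coordinate covariance in
population form (divisor $n$); orientation of the major axis in
$(-\pi/2, \pi/2]$; elongation $= \mathrm{sd_{major}}/\mathrm{sd_{minor}}$;
and a single size scalar
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sqrt{\mathrm{sd_{major}}\,\mathrm{sd_{minor}}}$
— the FWHM of the Gaussian whose geometric-mean spread matches the
cluster, chosen so that the statistic is rotation-invariant and reduces
to the usual $2.355\,\sigma$ for circular clusters. Convex-hull area
uses the exact hull (0 for degenerate sets); when a label image is
available (KDE segmentations), the mask area in nm² is reported as
well. Degenerate clusters yield `NA` elongation/orientation rather than
errors. All features are translation-invariant; all but orientation are
rotation-invariant (asserted to $10^{-9}$ relative in the tests).

## Template-free particle averaging

Many copies of one structure are aligned by features of a reference
channel, not by iterative all-to-all registration: the centre of mass
(photon-weighted when photon counts exist) is translated to the origin,
the major covariance eigenvector is rotated onto the x-axis, and the
half-plane carrying more mass ends on the left. Using the localization
covariance rather than image moments avoids any dependence on a pixel
grid.

The principal axis leaves a 180° ambiguity, and reflection adds a
mirror ambiguity. The left/right mass rule resolves the first; with
the default settings the mirror ambiguity about the x-axis is left
unresolved, which is faithful to the display convention
(highest intensity left) but means a particle and its mirror image land
on poses differing by a y-flip. Passing `resolve_y = TRUE` applies a
second, top-heavy rule, selecting among the four candidate poses
(rotation by $\theta$ or $\theta + \pi$, mirrored or not) the
left-heavy one whose upper half carries more mass. Because the rule is
a deterministic function of the point set alone, every rigid or
mirrored copy of the same particle then lands on the *identical* pose,
which is what makes exact recovery testable: 50 simulated particles
under recorded random motions and mirrors re-align onto their canonical
twins to better than $10^{-6}$ nm. Half-plane masses are counts (or
photon sums); exactly balanced counts — possible with even $n$ — fall
back to the per-side second moment, which is not constrained by the
centring (first moments vanish identically) and is invariant across
copies.

Round particles (elongation below 1.1) have a noise-dominated principal
axis; they are aligned anyway but flagged `orientation_unreliable`.
Particles whose reference channel has coincident localizations cannot
be aligned and are skipped with a report. Averaging offers both
`merged_render` (one KDE of the pooled localizations) and
`mean_of_renders` (pixel-wise mean of per-particle KDEs); whether the
pooled or per-particle route better matches a given display is a matter
of taste, so both are provided.

## Synthetic data: what it emulates and what it does not

The generators are the package's only data source for validation, so
their scope matters. They emulate a dSTORM-like field: isotropic
Gaussian clusters ("circular" is read as isotropic; a uniform-disc mode
exists as an option) over uniform background noise, with precisions
drawn from a lognormal distribution with median 10 nm and
$\sigma_{\log} = 0.3$ — typical of data with 10–20 nm resolution. They
do **not** simulate blinking kinetics, repeated emitters across frames,
drift, or camera noise, so passing tests demonstrate the correctness of
the algorithms on idealized point data, not robustness to those
artefacts (drift and grouping errors are exactly what the scatter
visualization is meant to expose manually).

The benchmark composition is fixed: six isolated clusters of 50
localizations, one component of 100 localizations formed by two
overlapping clusters, 300 noise points — 700 rows, with per-row ground
truth. Counts are exact by construction, never stochastic. The
geometry is this package's choice of a realistic scale, declared once:
3000 nm field, 25 nm cluster spread, 60 nm overlap offset (within
$4\sigma$ so the pair genuinely fuses), 400 nm minimum centre
separation, centres placed by rejection sampling.

Elongated test particles for averaging are built in canonical frame
with Gaussian width and a zero-mean two-lobe half-normal mixture along
the long axis: a fraction `left_fraction` of points in a narrow dense
left lobe balanced by a wide sparse right lobe. This makes the particle
centred (so the centroid is at the origin) while keeping a count
majority on the left *about the centroid* — a subtlety that matters,
because a distribution asymmetric only about the origin loses nearly
all its count asymmetry after centring, leaving the orientation rule
balanced on a knife edge. The recorded rotation/translation/mirror of
every copy is returned for recovery testing.

All generators are pure functions of their configuration and seed and
replay bit-identically; they restore the caller's RNG state.

## Problem sizes and test design

The test suite validates each operation against an independent oracle
(brute-force DBSCAN, unpruned whole-set bisector clipping with shoelace
areas, queue-based flood fill, hand-computed eigen-decompositions)
rather than against stored outputs. Sizes were chosen to exercise the
algorithms well inside a laptop-scale budget: 100 random DBSCAN
instances up to $n = 200$; 20 Voronoi instances up to $n = 120$
(the brute oracle is cubic); 20 simulated 700-localization benchmark
fields per clustering route; 50 particles of 300 localizations for
averaging recovery. The full suite runs in well under a minute.

## Known limitations

* Strictly 2D. 3D data can only be visualized via the scatter plot's
  colour/size channel; clustering and alignment are planar.
* No drift correction or blink grouping; these belong upstream.
* Proprietary binary formats (Zeiss ZEN, ImageJ `.roi`) are not parsed;
  the generic column mapping covers any delimited export.
* Spatial statistics that describe clustering globally (Ripley's K,
  pair correlation) are out of scope; dedicated point-pattern packages
  serve that need.
* The KDE mass guarantee assumes the 5-bandwidth margin; fields cropped
  tighter lose kernel mass at the edges by design.
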