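---
title: "Quantifying gamma-H2AX DNA-damage foci: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gamma-H2AX DNA-damage foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fociquant)
```

## The measurement problem

Ionizing radiation produces DNA double-strand breaks (DSBs). Cells mark
each break by phosphorylating the histone variant H2AX over megabase
stretches of chromatin; immunostained γ-H2AX appears as bright nuclear
*foci*, and counting, sizing and localizing those foci over time reads
out the damage load and the repair kinetics. Two imaging modalities see
the same biology at different scales:

* **3D confocal microscopy** resolves micron-scale foci in whole nuclei.
  The readout is per-nucleus: how many foci, at what density
  (count per nucleus volume, µm⁻³), and how large (µm³).
* **dSTORM single-molecule localization microscopy** resolves the
  ~40–50 nm substructure inside each focus. The raw datum is a table of
  blink localizations; the readouts are cluster densities (µm⁻²),
  convex-hull cluster areas (µm²), nearest-neighbor distances,
  radial distribution within the nucleus, cluster coverage of the
  nucleus, and — after photophysical calibration — the number of labeled
  epitopes per cluster.

`fociquant` implements both branches, plus seeded scene generators that
produce synthetic inputs with exact ground truth so that every stage can
be validated end to end.

## Confocal branch

### Foreground threshold (maximum entropy)

Foci are separated from background with the Kapur maximum-entropy
criterion: for a candidate threshold $t$, split the intensity histogram
into background ($I \le t$) and foreground ($I > t$), and pick the $t$
maximizing the sum of the Shannon entropies of the two normalized
partitions. Ties break toward the smallest $t$. The threshold is
computed once from the whole 3D stack's histogram and applied globally,
so a stack has a single operational definition of "focus signal".
Images with up to 256 distinct values are thresholded over those exact
values; continuous data are binned into 256 equal-width levels.
A constant image has no valid split and is an error.

### Clusters, noise filter, association

Voxels above threshold are grouped into connected components —
26-connectivity by default (faces, edges, corners; configurable to 18
or 6) since that is the most permissive reading of "connected voxels".
Components under 5 voxels are discarded as noise; at the default
acquisition geometry of $0.21 \times 0.21 \times 0.3$ µm voxels that
cutoff equals $0.06615$ µm³. (The voxel size itself is a configuration
default inferred from that worked value, not a measured constant; set it
per dataset.) Each surviving cluster is summarized by its voxel count,
physical volume and centroid, and is attributed to the nucleus label
found under its centroid — clusters are never split across nuclei, and
centroids over background are reported separately as unassigned.

### Nucleus segmentation

The DAPI channel is binarized slice-wise: linear contrast stretch
between the 1st and 99th stack percentiles, Gaussian smoothing
(σ = 2 px), then one global threshold for all slices, computed as the
mean of the Bradley local adaptive threshold surface on the single slice
with the highest summed intensity. The Bradley surface is the local box
mean (window = slice width / 8) plus a sensitivity offset of 10% of the
stretched dynamic range; both are configurable. The mask is cleaned by
dilation (disk r = 2 px), hole filling, and a morphological opening
(disk r = 10 px).

Touching nuclei are split by marker-controlled watershed on the negated
Euclidean distance transform. Plain watershed oversegments, so shallow
extrema are suppressed first: markers are the regional maxima of the
h-maxima transform of the distance map (reconstruction by dilation of
$D - h$ under $D$), with depth $h = 2$ distance-transform voxels by
default. The recipe runs per slice first and is then repeated on the
compiled 3D volume; single-slice distance maps separate touching nuclei
more reliably than the anisotropic volume does directly. Ridge voxels
where two basins meet stay unlabeled, so labels plus ridges exactly
partition the binary foreground.

Segmented objects are filtered by volume (default 100–10,000 µm³),
surface/volume ratio (default max 1.5 µm⁻¹; the surface estimate is the
exposed-voxel-face count times face area — deterministic and simple,
systematically above the smooth-surface area by a known
voxelization factor), and boundary contact (objects protruding from the
imaged volume are removed by default).

### Resolvability limit of threshold-based foci counting

Two Gaussian foci of amplitude $A$ on background $b$ merge under any
single global threshold once their separation leaves no intensity
valley below that threshold. At the package defaults
($A = 80$, $b = 10$, Kapur threshold ≈ 30) the midpoint of two foci
4σ apart reaches $2A e^{-2} + b \approx 38$ — above the threshold, so a
4σ pair is *provably* unresolvable by connected components, before any
noise. The synthetic-scene generator therefore enforces a minimum
center separation of 5σ between foci of one nucleus, measured in
per-axis sigma units (the axial width σ_z = 0.25 µm exceeds the lateral
σ_xy = 0.2 µm, so an isotropic distance would under-separate axial
neighbors). Passing recovery tests on these scenes show the pipeline is
correct for resolvable foci; they deliberately say nothing about the
merged-foci regime, which the confocal modality cannot disambiguate —
that is precisely the gap the dSTORM branch addresses.

## dSTORM branch

### Drift correction

Long acquisitions drift mechanically and thermally. The blind
correction renders temporal bins of 2,000 frames (default) as 2D
position histograms at 10 nm pixels, estimates each bin's shift against
the first bin at the cross-correlation peak with parabolic sub-pixel
refinement, interpolates the shifts linearly to individual frames
(extrapolating the end segments with the adjacent slopes, so drift
beyond the outer bin centers is not clipped), and subtracts them.
Corrected coordinates are added as columns; every downstream step uses
them when present. A single bin is the identity; a bin with fewer than
50 localizations is an error suggesting larger bins.

### Clustering and geometric metrics

Clusters are found with standard DBSCAN. Two presets matter, both
config-exposed:

* **foci-level** (`eps` = 50 nm, `minPts` = 10): isolates repair-focus
  substructure clusters of the ~0.15–0.4 µm² scale. `eps` sits above
  the localization precision (~10 nm) and the ~40–50 nm apparent size
  of a single labeled structure.
* **subunit-level** (`eps` = 15 nm, `minPts` = 5): isolates individual
  blink clusters; used for photophysical calibration (below).

Cluster area is the convex hull of the member localizations (shoelace
formula on the hull vertices, nm² → µm²); sets with fewer than three
non-collinear points get area 0 and a degenerate flag. The cluster
position is the arithmetic mean of member coordinates. Nucleus regions
come from the widefield image via the same slice-segmentation recipe and
2D watershed; clusters attach to the region containing their center.
Per-nucleus metrics: cluster density (count/area), nearest-neighbor
distances between cluster centers (grid-accelerated, with per-nucleus
medians), coverage (Σ hull areas / nucleus area), and a radial profile
in five concentric equal-area zones built from quantiles of the
normalized interior distance transform (zone 1 at the center, zone 5 at
the envelope). Equal-area zones were chosen over equal-width annuli so
the flat-profile null hypothesis is a plain equal-expectation chi-square;
the construction is validated on a disk to 2% discretization tolerance.

### Epitope counting and the blinking model

A single labeled epitope produces a random number of localizations: it
carries $D \sim \mathrm{Binomial}(M, \eta)$ detected dyes (default
$M = 3$ maximum dye sites, labeling efficiency $\eta$), and each dye
yields $\mathrm{Geometric}(q)$ localizations on support
$\{1, 2, \dots\}$ (mean $1/q$; a dye that never appears is absorbed
into $\eta$). The localization count of a detected ($D \ge 1$) epitope
is then a binomial mixture of shifted negative binomials, with mean

$$\mu = \frac{E[D \mid D \ge 1]}{q} = \frac{M\eta}{(1 - (1-\eta)^M)\, q}.$$

$\mu$ is the imaging system's response function; dividing a cluster's
localization count by $\mu$ and rounding gives its epitope estimate
(floor of one for any detected cluster). Because dye photophysics vary
with illumination intensity across the field, $\mu$ is fitted per tile
of a 4 × 4 grid by default; a cluster in a tile without a fit is a hard
error rather than a silent global fallback (the pipeline runner, by
contrast, falls back to one pooled fit with a warning, which is the
pragmatic choice for exploratory runs).

Three numerical points, each of which measurably changed accuracy during
development:

* **Truncation.** Calibration counts come from cluster detection, so
  counts below `minPts` are never observed. The likelihood is
  left-truncated at the detection floor; ignoring this biased the
  fitted mean upward severely. Calibration uses the subunit preset
  (floor 5), keeping ~70% of the single-epitope count distribution in
  view rather than ~35% at the foci-level floor of 10.
* **Calibration selection.** Single-epitope candidates are selected by
  apparent size — the Gaussian FWHM implied by the RMS radial scatter of
  member localizations, cutoff 60 nm — not by convex-hull extent. A hull
  extent grows with the localization count, so a hull cutoff silently
  removes bright single epitopes and right-truncates the count
  histogram; the RMS measure is count-independent and also rejects
  merged epitope pairs (their scatter is inflated by the pair
  separation).
* **Optimization.** The $(\eta, q)$ likelihood surface has ridges —
  $\mu$ is well identified while $\eta$ and $q$ individually are not —
  and a single Nelder-Mead start can stall on a local optimum. The fit
  takes the best of a small grid of starts. With $M = 1$ and no
  truncation the MLE is closed-form ($\hat q = 1/\bar n$).

The model family is a deliberate, documented stand-in: it is the
simplest compound model consistent with dye photophysics (finite dye
sites, incomplete labeling, geometric reactivation), and it is pluggable
behind `fit_epitope_model()`.

## Synthetic scenes: what they emulate, and what they do not

**Confocal generator.** Non-overlapping ellipsoidal nuclei (semi-axes
≈ 6.5 × 4.5 × 2.2 µm, 10% jitter — glioblastoma-like nuclei of a few
hundred µm³) filled with multiplicatively textured DAPI signal; foci as
3D Gaussian blobs (σ_xy = 0.2 µm, σ_z = 0.25 µm, amplitude 80 photons
over a 10-photon background) with Poisson-distributed counts per nucleus
(λ = 50, the scale of an irradiated nucleus at 30 min); both channels
get Poisson shot noise plus Gaussian read noise (SD 2). Placement is
rejection sampling with an explicit attempt budget; failure is a named
error, not a silent shortfall.

**dSTORM generator.** One polygonal nucleus (~150 µm²); cluster centers
uniform inside it; epitopes scattered around centers with a Gaussian
(default σ 100 nm, truncated to the polygon); the compound blink model
above ($M = 3$, $\eta = 0.6$, $q = 0.2$ defaults, ~20,000 frames,
precision 10 nm); optional linear stage drift; frames uniform at random.
`q` may be supplied as a function of position to emulate inhomogeneous
illumination. A widefield image is rendered from the localization
density plus a nucleus fill.

Not emulated, by design: optical PSF physics, spectral crosstalk,
EM-gain statistics, realistic chromatin texture, ON-time frame
correlation, or repulsive/attractive focus placement beyond the minimum
separation. Tests passing on these scenes certify the algorithms under
the stated generative assumptions; real data can violate them (e.g.
clustered blinking inflates apparent epitope counts at short
acquisitions).

## Reporting conventions

Foci density is reported per volume (µm⁻³) in the confocal branch and
per area (µm⁻²) in the dSTORM branch — the two modalities measure
different geometry. Summaries report mean, median and the 25th/75th
percentiles with the linear-interpolation quantile convention (R type 7),
pinned by test. Long-format exports are one row per observation and
round-trip losslessly. Every pipeline run writes a provenance block
(package version, seed, full configuration) sufficient to reproduce it.

## Problem sizes used in validation

The test suite and the acceptance script validate at these scales, each
chosen as the smallest size at which the statistical claims are stable:
full confocal scenes of 512 × 512 × 20 voxels with 20 nuclei at
λ = 50 foci; drift recovery on an ~10⁵-localization acquisition
(150 clusters × 75 epitopes); blink calibration on 2,400 single-epitope
clusters with epitope counting on clusters of 5–500 epitopes; oracle
cross-checks on 100 random histograms, 50 random 3D masks, 20 DBSCAN
instances up to 1,000 points; and 100 simulated CSR nuclei for radial
flatness.

## Known limitations

* Counts in the merged-foci regime (confocal, spacing below ~5σ) are
  lower bounds. At high dose, focus density rises until neighboring foci
  overlap and the detected count *drops* while detected volumes grow —
  an expected artifact of diffraction-limited counting, not a bug.
* Epitope estimates inherit a small negative bias of
  $1 - (1-\eta)^M$ (undetected epitopes cannot be counted); at the
  defaults this is ≈ 6%.
* Drift correction assumes structure-rich fields; a nearly empty
  localization table gives noisy shift estimates.
* The per-cluster epitope estimate divides by $\mu$ rather than fitting
  each cluster's count distribution; for clusters of a few epitopes the
  rounding dominates the error.
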