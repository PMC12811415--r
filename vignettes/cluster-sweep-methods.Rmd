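---
title: "Methods: density-based cluster sweeps for two-channel SMLM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: density-based cluster sweeps for two-channel SMLM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmsweep)
```

## The model and its assumptions

Single-molecule localization microscopy reduces an image series to a
point pattern: one row per detected fluorophore emission, with x–y
coordinates (nm) and a localization uncertainty (nm).  `smlmsweep`
analyzes such patterns for two channels — channel A labels the CBM3a
module of the primary cellulosome scaffoldin (CipA), channel B labels
unoccupied type I cohesins — under three assumptions:

* the pattern is two-dimensional (axial structure is projected away);
* one *emitter* (one labeled molecule) produces several localizations
  through blinking, so absolute localization counts overestimate
  molecule counts by the mean blinking multiplicity;
* spatial organization of interest lives at scales of tens to hundreds
  of nanometres, between the localization precision (~10–35 nm) and the
  cell size (~1–3 µm).

**Clustering.** We use DBSCAN with the classical core/border/noise
semantics.  With epsilon radius $\varepsilon$ and a minimum number of
molecules $m$ (MNM), a localization is *core* when its closed
$\varepsilon$-neighbourhood (Euclidean distance $\le \varepsilon$,
the point itself included) contains at least $m$ localizations.
Clusters are the connected components of the core points under the
$\varepsilon$-neighbourhood relation; non-core points within
$\varepsilon$ of a cluster's core are *border* members; the rest is
*noise*.  Both conventions (closed neighbourhood, self-counting) follow
the original formulation of the algorithm and the behaviour of the
widely used library implementations; neither is universal, so they are
stated here and enforced by tests against an $O(n^2)$ brute-force
reference.

**The sweep statistic.** For a region of interest (one cell, say), we
compute the number of detected clusters $C(m)$ over a grid of MNM
values at fixed $\varepsilon$, and rescale to $\hat C(m) = C(m) /
\max_m C(m)$ so each cell's profile peaks at 1.  Averaging $\hat C$
over many cells gives a per-condition aggregate profile, and the
*modal MNM* — the grid value maximizing the mean normalized profile —
summarizes how many molecules the typical cluster packs into an
$\varepsilon$-disc.  Dense, large clusters keep their identity up to
large $m$ (high modal MNM); sparse or small clusters dissolve early.
A second mechanism matters on densely decorated cells: at very low $m$
a diffuse surface labeling bridges adjacent clusters into a single
connected component, so $C(m)$ can *rise* before it falls, placing the
mode at an interior grid value.

## Tunable parameters

| parameter | unit | default | rationale |
|---|---|---|---|
| `eps` (channel A) | nm | 75 | upper bound of CBM3a–CBM3a distances between neighbouring complexes, plus localization precision |
| `eps` (channel B) | nm | 125 | sparser GFP–dockerin labeling needs a wider neighbourhood |
| MNM grid | molecules | 10–1200; step 10 to 100, then 50 | the analysis range; spacing is a package choice balancing resolution against runtime |
| `max_uncertainty` | nm | none | precision cutoffs are instrument-specific; the filter is inclusive (≤) and keep-more by default |
| coloc `d` | nm | 75 | tied to the channel-A clustering scale; overlay-image "yellow" colocalization defines no distance, so this is declared, not derived |
| normalization | — | `"max"` | per-cell peak scaled to 1; `"sum"` (profile sums to 1) available |

The normalization denominator is genuinely open: "normalized to 1"
admits per-cell-peak or pooled readings.  We normalize per cell and
then average (so every cell contributes equally regardless of its
absolute cluster count), and expose pooled behaviour by aggregating a
single profile computed on merged tables.

## The synthetic generator: what it emulates, and what not

`simulate_scene(preset, seed)` builds a stated world:

* **Geometry.** Cells are 2D capsules (projected rods, default 2.4 µm
  spine, 400 nm radius); substrate particles are polygons; EMS contact
  zones are polygons that must touch a cell outline and a particle.
* **Planted clusters.** Per surface class (cell perimeter band,
  particle boundary, contact-zone interior), cluster counts are
  Poisson and sizes (CipA count) lognormal; positions are isotropic
  Gaussian around the center (dispersion 40 nm) — DBSCAN is
  shape-agnostic, so no protuberance shape model is attempted.
* **Stoichiometry.** Each CipA yields a channel-A emitter with
  probability `label_eff_A` (0.8); its 9 type I cohesins are each
  occupied by an enzyme with probability `occupancy_prob` (0.9, cells
  being nearly saturated), and each unoccupied cohesin yields a
  channel-B emitter with probability `label_eff_B` (0.8).  The anchor
  valency enters only through `max_enzyme_capacity()` (7 × 9 = 63).
* **Photophysics.** Each emitter produces `1 + Geometric` localizations
  (mean 5) — the simplest memoryless blinking model — displaced by
  isotropic Gaussian error (σ = 20 nm); per-localization uncertainties
  are Gamma-distributed around σ.
* **Background.** Two components, both ground-truth-labeled as
  background: a homogeneous Poisson field (2 µm⁻² per channel) standing
  in for unclustered noise, and a diffuse *cell-surface* emitter rate
  (per µm of perimeter) that models non-punctate wall labeling.  The
  surface component is what makes log-phase cells "interconnected" at
  low MNM; it is deliberately not counted as a planted cluster.

Preset magnitudes are synthetic choices, fixed once and documented
here, not measurements: log-phase presets use ~8 cell-surface clusters
of ~80 CipA and a surface rate of 30 emitters/µm; stationary presets
use ~3 clusters of ~20–25 CipA and 6–8 emitters/µm; `stationary_bound`
moves most cluster mass into the contact zone.  These encode the
qualitative contrasts the analysis is meant to resolve (more/larger
clusters in log phase; relocation to the substrate interface in
stationary phase on cellulose).  Because absolute emitter densities
per protuberance are not measurable from published figures, a green
end-to-end test establishes that the *pipeline* recovers the planted
contrast — not that the magnitudes match any real culture.  The
generator also omits: frame-resolved photophysics (the `frame` column
is uniform), drift, detector artifacts, 3D structure, and
cluster-shape anisotropy.

## Numerical choices

* Distances and the uncertainty filter use inclusive boundaries
  (≤); two points exactly $\varepsilon$ apart are neighbours
  ("maximum center-to-center distance" implies inclusion).
* Cluster ids are dense integers from 0 in order of discovery; noise
  is −1.  A border point reachable from several clusters goes to the
  cluster whose expansion reaches it first in input order — the
  original algorithm's behaviour, made explicit so labelings are
  reproducible.  Core sets and the core partition are
  order-invariant; tests assert both.
* Neighbour search bins points into a grid of cell size
  $\varepsilon$ and scans the 3×3 block; the brute-force scan is the
  test oracle, any internal strategy is contractually equivalent.
  A sweep computes neighbour lists once per ($\varepsilon$, table).
* Point-in-polygon is even-odd with an explicit on-segment test
  (relative tolerance 10⁻⁹), so boundary points are inside; when two
  ROIs share an edge, `assign_rois()` gives the point to the earlier
  ROI, which makes disjoint partitions conserve counts.
* Degenerate inputs: an empty point set clusters to an empty labeling
  (not an error); an all-zero count profile normalizes to all zeros;
  modal-MNM ties break toward the smallest grid value; an empty
  channel reports colocalization 0 with `n = 0` flagging it.
* All randomness flows from one integer seed, expanded per stage by a
  multiplicative-congruential step kept below $2^{31}$; identical
  (preset, params, seed) reproduce tables bit for bit.

## Validation strategy

Every operation with a nontrivial contract is tested against an
independent oracle: DBSCAN against a full-distance-matrix reference
(core sets and core partitions must match exactly, 100+ random
instances), `mnm = 1` against union-find connected components,
clipping against a winding-number point-in-polygon, areas against the
cross product, colocalization against all-pairs scans, aggregation
against direct sums.  Recovery tests plant well-separated clusters
(separation > $4(\varepsilon + 3\sigma)$) and require exact cluster
counts; the end-to-end test requires the `stationary_detached` modal
MNM to fall strictly below `log_bound`'s in ≥ 90% of seed pairs.

## Known limitations

* Blinking is memoryless; real fluorophore duty cycles are not, so
  absolute molecule-count calibration is out of scope.
* The published per-image cluster counts (e.g. 205 clusters at
  MNM = 40) depend on raw localization data that are not publicly
  deposited; they are not reproduction targets, and no attempt is made
  to match them.
* Colocalization is coordinate-based; pixel-overlap coefficients
  (Pearson/Manders) are deliberately not provided.
* DBSCAN parameters are user choices; the package provides the sweep
  precisely so conclusions need not hinge on a single MNM, but it does
  not auto-select $\varepsilon$.
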