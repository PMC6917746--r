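---
title: "Models and methods behind gastruflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gastruflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gastruflow)
```

`gastruflow` analyses single-cell trajectories and image stacks from
pan-embryo recordings of zebrafish gastrulation. This vignette documents
the models the package implements, the parameters that matter, what the
synthetic embryo does and does not emulate, and the numerical decisions
taken where the design was genuinely open.

## Coordinate system

All statistics live in an embryo-centric spherical frame
(`spherical_frame()`): the centre and radius of the best-fit embryo
sphere, a unit animal-axis and an orthogonal dorsal axis. Latitude
$\phi \in [-\pi/2, \pi/2]$ has the animal pole at $-\pi/2$, so epiboly
(animal-to-vegetal spreading) increases $\phi$; longitude
$\theta \in (-\pi, \pi]$ has the dorsal midline (shield) at $0$, so
convergence decreases $|\theta|$. Flow analyses work in the conformal
Mercator plane $u = \theta$, $v = \ln\tan(\pi/4 + \phi/2)$. Latitudes are
clamped at $\pm 85^\circ$ (`phi_max = 1.4835` rad) so poles never produce
infinities; clamped points are retained and counted, never dropped.
Because the projection is conformal, the tangent directions of pure
epiboly and pure convergence map to the constant plane vectors $(0, 1)$
and $(-\operatorname{sign} u, 0)$, which is what makes the decomposition
below cheap and exact at grid centres.

A note on area: a plane grid cell at latitude $\phi$ represents only
$\cos^2\phi$ of sphere area. Counts collected on the plane grid from a
uniformly covered sphere therefore scale as $\cos^2\phi$, and comparing
densities across latitudes requires multiplying counts by the Mercator
area inflation $\sec^2\phi$ (`area_factor()`). The package applies the
correction in this direction throughout (streamline widths, density
checks); it is the only direction under which uniformly distributed
sphere samples give uniform corrected counts, which the test suite
verifies by Monte-Carlo.

## The synthetic embryo

`simulate_embryo_tracks()` generates the study conditions every
downstream stage is tested against: `n_cells` cells in a shell of
thickness `shell_band` (50 µm) under the surface of a 350 µm embryo
sphere (inside a 550 µm chorion), advected from `t_start = 4` to
`t_end = 14` hpf at `frame_interval = 120` s. The imaging protocol this
emulates states both 150 s and 2 min stack intervals; 120 s is the
configurable default, and nothing downstream depends on the choice. Flow
profiles default to smooth bumps — epiboly peaking around 5–9 hpf
(0.35 rad/h peak), convergence around 8–12 hpf (0.18 rad/h) — chosen as
qualitatively realistic defaults; no quantitative magnitudes are asserted
against external data. Mesendoderm-lineage cells sit deeper in the shell
than epiblast cells, giving the radial stratification the
`mean_radial_position()` statistic measures.

Internalisation is deterministic for testability: flags are drawn
Bernoulli(`internalize_fraction`) over the mesendoderm lineage, flagged
cells are seeded near the shield (longitude ~ N(0, π/8), latitude near
the margin), step radially inward by `internalize_depth` (30 µm) over
`internalize_ramp_h` (0.5 h) starting at `internalize_time` (6 hpf), and
then drift animal-ward at `animal_drift_rate` (0.3 rad/h). Stochastic
cell-autonomous switching was rejected: ground-truth labels must be
unambiguous for recount oracles. Expression traces are first-order rises
$1 - e^{-(t - t_0)/\tau}$ after onset (*mezzo* 4.5 hpf in the mesendoderm
lineage, *sox17* 6.5 hpf in endoderm, $\tau$ = 0.5 h), kept noise-free so
monotonicity is an invariant.

Randomness uses one substream per cell, derived from `(seed, cell
counter)`, so simulating more cells never perturbs existing ones and
identical seeds give bit-identical output. Initial positions are
rejection-sampled against already placed cells with a `min_spacing` of
12 µm: nuclei sit inside ~10 µm cell bodies and cannot overlap, and
without this constraint the channel-subtraction recount would be degraded
by physically impossible nucleus-in-neighbour-cytoplasm configurations
rather than by any property of the method.

What the simulator does **not** emulate: realistic point-spread functions
and light-sheet shadowing, cell division (only `parent_id` bookkeeping),
cell-cell mechanical interactions after placement, expression noise, and
tissue-scale fluctuations in the flow. Tests passing on this generator
show the analysis chain is correct under its stated model; they do not
show robustness to segmentation errors or optical artefacts in real
recordings.

## Image-side computations

**Focus filtering.** `dog_filter()` computes $|I - G_\sigma * I|$ with a
2D Gaussian per z-plane, $\sigma = 1$ voxel by default. A 3×3 plane-wise
median follows before thresholding in the sphere fit; the median is
implemented as a vectorised min/max comparator network because a
per-pixel sorting filter is two orders of magnitude too slow at the stack
sizes involved (a 289³ transmission stack at 4 µm voxels).

**Two-sphere fit.** `fit_two_spheres()` is a k-means-style EM loop over
foreground voxels: the E-step assigns each voxel to the sphere whose
*surface* is nearest, $|\,\lVert p - c\rVert - r\,|$, with ties going to
the smaller (embryo) sphere so the assignment is deterministic; the
M-step refits each sphere by the algebraic least-squares fit and then
re-estimates the radius as the mean distance to the fitted centre — the
exact minimiser of the squared surface-distance objective given the
centre — which keeps the recorded objective non-increasing in practice.
Initialisation: both centres at the image centre, radii 350/550 µm. The
foreground threshold was a manual setting in the original acquisition
context; here it is an exposed parameter defaulting to the 99th intensity
percentile. Degenerate cases: an emptied assignment or a coplanar point
set flags the affected sphere unconverged with the iteration index;
fewer than 20 foreground voxels is an error.

**Shell mask and storage.** `shell_mask()` selects voxels with signed
surface distance in `[inner, outer)` (default ±150 µm, a 300 µm shell)
and stores their linear indices once; `masked_write()` then stores one
binary blob of intensities per timepoint in index order (float64,
little-endian), with shape, dtype, band, sphere and index order recorded
in a JSON header. Indices are R's native column-major order (x fastest);
the order is declared in the header rather than imposed as z-major, which
would force a permutation on every access. A blob whose length disagrees
with the index table raises an error naming both lengths.

**Nucleus detection.** `detect_nuclei()` smooths (σ = 1), takes strict
26-neighbourhood maxima above threshold 150, and removes maxima not
separated from any higher maximum by a saddle at least 30 gray levels
deep. "Separated by at least 30 gray levels" is ambiguous between
absolute height difference and saddle prominence; prominence is
implemented (and verified against a brute-force superlevel-set flood),
since absolute difference would delete distinct nuclei of similar
brightness. Only voxels above `threshold − min_prominence` can influence
the decision, so the union-find flood is restricted to that superlevel
set.

**Registration.** `rigid_register()` is standard ICP: brute-force nearest
neighbours, Kabsch SVD solve with $\det R = +1$ enforced, iterate to an
RMS change below `tol` (1e-9 µm). An optional trimmed variant drops the
worst fraction of correspondences per iteration; the default uses all
points.

**Channel subtraction.** With nuclear channels for all cells (ch3) and
endoderm (ch1) and a cytoplasmic mesendoderm channel (ch2):
epiblast = ⌊ch3 − s·close(ch2)⌋₊, mesendoderm = ⌊ch3 − epiblast⌋₊,
mesoderm = ⌊mesendoderm − s′·ch1⌋₊, endoderm = ch1. Two judgement calls:
channels are rescaled so their 99.9th-percentile intensities match before
subtraction (raw subtraction across fluorophores is meaningless), and the
cytoplasmic channel is grayscale-closed with a nucleus-sized element so
cytoplasmic signal covers the nuclear holes it must cancel.

**Expression readout.** Mean over a 3×3×3 voxel window (truncated at
edges), min–max normalised globally across all frames and positions of a
run; a zero dynamic range yields all zeros with a warning.

## Track statistics

The straightness index of track $i$ is
$SI = \lVert x_i(N_i) - x_i(1)\rVert \big/ \sum_k \lVert x_i(k{+}1) -
x_i(k)\rVert$, in $[0,1]$, invariant under rigid transforms and global
scaling; stationary tracks (zero path length) are undefined, flagged and
excluded from aggregates. SI-versus-position scatter uses non-overlapping
10-frame windows aligned to the track start — overlapping windows would
autocorrelate the scatter — with the window midpoint's spherical
coordinates as position. Per layer and coordinate, 90% prediction
ellipses assume bivariate normality: centre at the sample mean, shape
from the sample covariance, squared Mahalanobis radius
$\chi^2_2(0.90)$ (semi-axes scale by ≈ 2.146); fewer than three windows
in a layer yields no ellipse, flagged.

Radius/latitude drifts are last-minus-first differences over
non-overlapping 10-minute pieces, averaged per track; shorter tracks are
excluded and counted. Region filtering keeps tracks whose longitudes stay
in $[-\pi/8, \pi/8]$ (the shield window) within a time range, optionally
requiring full-window coverage. Latitude-profile clustering is Lloyd
k-means (default k = 3) on the per-frame latitude vectors with
deterministic initial centres (profiles at evenly spaced ranks of mean
latitude); missing frames are not permitted, so the completeness filter
must run first. The cluster that reverses latitudinal direction — sign
change of the smoothed (5-frame moving average) derivative of its mean
profile, preferring vegetal-then-animal — identifies the internalising
population. Note that raw profiles separate motion modes only among
tracks with comparable starting latitudes; the intended use, as in the
shield-region analyses, selects the margin band first.

Fragmented tracklets are re-joined by `aggregate_long_tracks()`, a
deliberately simple stand-in for statistical tracklet aggregation
methods: candidate end-to-start links within `gap_frames` (3) and
`link_radius` (15 µm) are accepted greedily by increasing distance (ties
by lower cell id), each endpoint used once.

## Flow fields and cross-layer statistics

`build_flow_field()` assigns each consecutive-frame displacement, taken
in the Mercator plane (wrapped $\Delta u$, $\Delta v$) and
unit-normalised, to the 40×40 grid cell of its **start point** (the
passing-through convention is ambiguous; start-point is chosen and
conserved: weights sum exactly to the number of retained displacements)
and to one of 10 time intervals spanning the track set's duration — about
1.5 h each for a 14–15 h recording, rather than a hard-coded 1.5 h.
Per-cell vectors are means of unit vectors, stored as a unit direction
plus resultant length (coherence); zero-length displacements are skipped
and counted. Multi-embryo averaging renormalises the mean of per-embryo
unit vectors and sums weights; exact cancellation is flagged incoherent.

Circular correlation between two layers' fields uses
$\rho = E[\sin\alpha\,\sin\beta] / \sqrt{E[\sin^2\alpha]\,
E[\sin^2\beta]}$ with both central directions fixed at 0, since they are
not identifiable for near-uniform direction distributions. The second
moments are taken about that fixed 0 (not mean-centred): this is the only
reading with $\rho(\alpha,\alpha) = 1$ exactly. Site pairs are weighted
by $\min(w_A, w_B)$ — the evidence for a pair is bounded by its weaker
member; this summarisation choice is declared, not derived.

The decomposition projects the unit flow direction onto the epiboly and
convergence references, $s = v \cdot \mathrm{ref} = \cos\angle$, and maps
$p = 1 - \tfrac{2}{\pi}\arccos(s)$ for $s > 0$, else $0$. The
$2/\pi$ normalisation is deliberate: the raw form $1 - 2\cos^{-1}(s)$
escapes $[0,1]$ for angles beyond about 29°, which contradicts the
quantity being a proportion; the adopted map preserves the limiting cases
($p(1) = 1$, $p(0) = 0$, $p(\cos 45^\circ) = 0.5$) and is linear in the
angle. Sites with a degenerate convergence reference (on the dorsal and
ventral meridians) are excluded from the convergence sums of the weighted
summary $o(t) = \sum_x p\,w / \sum_x w$, which is a convex combination of
site proportions by construction.

Streamlines integrate the direction field with fixed-step RK2 (midpoint),
step = ¼ cell width, at most 200 steps, bilinear interpolation over
populated neighbours, terminating on empty regions or the grid boundary;
seeds sit at all populated cell centres and widths carry the
area-corrected start-cell counts.

Local motion correlation takes 10-minute end-to-end motion vectors per
cell and the mean vector of its k = 6 nearest neighbours (3D Euclidean —
geodesic distance would erase the radial separation between layers, which
is the point of the cross-layer variant), splits both into spherical
components, and computes Spearman correlations per component and time
point. Residual motion between layers subtracts the epiblast
neighbourhood mean from each mesendoderm cell's motion, expressed as arc
lengths ($\Delta r$, $r\cos\phi\,\Delta\theta$, $r\,\Delta\phi$, µm) so a
1 µm/min animal-ward differential drift appears as a −10 µm latitude
residual per 10-minute window; residuals are grid-averaged per interval
and the radial component, lost in 2D maps, is summarised as a kernel
density.

## Visualisation exports

Edge bundling follows the standard force-directed formulation: polylines
resampled to a doubling subdivision schedule over 6 cycles, step size
halved and iterations reduced by a third per cycle, spring forces along
each polyline plus attraction between corresponding vertices of
compatible pairs (angle × scale × position × visibility compatibility of
the endpoint chords, threshold 0.6), optional k-means pre-clustering so
bundling acts within spatial groups, endpoints pinned, everything
deterministic in input order. The stiffness and iteration counts are
declared defaults, not values inferred from any reference rendering; a
0.95 rendering transparency is carried in the parameters. Space-time
exports emit per-track $(u, v, t)$ polylines plus a vertical
stationary-reference line. The web-viewer JSON decimates vertices to one
fifth (endpoints kept), carries per-vertex expression clipped to
$[0, 1]$, and round-trips through a validating reader.

## Pipeline and reproducibility

`run_pipeline()` executes the enabled stages in dependency order from one
declarative `pipeline_config()`, writes every output with an MD5 manifest
and the effective configuration, skips re-runs whose manifest still
matches unless forced, validates inputs before any stage runs, and on
stage failure aborts naming the stage while retaining partial outputs.
Identical configuration and seed reproduce every hash; this is asserted
in the test suite. There is no shell entry point: the exported functions,
`scripts/acceptance.R`, and this vignette are the interface.

## Problem sizes

The test suite and acceptance script choose sizes that keep the full run
near a minute while leaving comfortable statistical margins: transmission
fits on 289³ stacks at 4 µm voxels, channel subtraction on 120-cell
embryos in 70³ stacks, decomposition switch recovery on 150-cell,
300-frame simulations over three seeds, residual-drift recovery with
1000 cells per layer, ellipse calibration at n = 10⁵, and Monte-Carlo
nulls at 1000 sites. Larger runs change nothing structurally; the
simulator and flow code scale linearly in cells × frames.

## Known limitations

- The sphere-fit M-step is algebraic, not a full geometric optimisation;
  its objective is observed monotone on realistic inputs but carries no
  proof.
- Latitude-profile clustering compares absolute profiles; populations
  with heterogeneous starting latitudes must be spatially filtered first.
- Nearest-neighbour searches are brute force, adequate to ~10⁴ cells per
  frame; beyond that a spatial index would be warranted.
- The channel-subtraction recount assumes non-overlapping nuclei; heavily
  confluent tissue would need a true segmentation.
- `aggregate_long_tracks()` is a greedy linker, not a statistical
  trajectory model; it recovers ≥ 90% of simulated fragment continuities
  but makes no global optimality claim.
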