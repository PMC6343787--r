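---
title: "Mesh-scan crystal cartography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesh-scan crystal cartography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshcarto)
```

`meshcarto` turns a two-dimensional X-ray diffraction mesh scan — one still
image per grid node, already reduced upstream to a diffraction score and a
spot list per node — into a ranked list of individual crystals with
positions, sizes and diffraction strengths, plus a per-node crystal map.
This vignette explains the underlying models, the package's conventions and
defaults, what the bundled simulator does and does not emulate, and the
design decisions taken where the method leaves room.

## Geometry conventions

The beam runs along +z and hits a flat detector normal to it at
`detector_distance` (mm). Detector pixels are 0-based and continuous; x is
the fast axis. A spot at pixel (x, y) has the scattered-ray unit vector
$\hat s$ from the sample through its lab position, and the diffraction
vector

$$\mathbf q = (\hat s - \hat z)/\lambda, \qquad |\mathbf q| = 2\sin\theta/\lambda .$$

Grid nodes are (row, col), 0-based. Shutterless mesh scans on modern
beamlines trigger the detector by rotating the goniometer slightly while
each **row** is collected, returning to the start angle for the next row.
The package therefore assigns

$$\omega(r, c) = \omega_{\mathrm{start}} + c\,\omega_{\mathrm{per\ image}},$$

with a per-row reset. This matters: pairs of stills taken at distant ω
cannot share reflections, so their similarity score saturates regardless of
whether they come from the same crystal. With the per-row convention,
ω-near pairs exist between any two grid neighbourhoods (Δω depends only on
the column difference), which is what lets the ω-gated clustering (below)
see through the saturation. A monotone ω over the whole scan would leave
almost all cross-row pairs gated out and make single homogeneous crystals
fall apart into per-row clusters.

## Multi-pattern detection

For each image the lengths of all $\binom{N}{2}$ difference diffraction
vectors (DDVs) $|\mathbf q_i - \mathbf q_j|$ are histogrammed into 100
half-open bins over $[0, 1/25)$ Å⁻¹ (overflow discarded; only this short
range is analysed). A single lattice yields counts only at the discrete
lengths of short lattice vectors; two superposed lattices add inter-lattice
differences whose length distribution is smooth and, over this range,
approximately linear in ℓ (the pair-distance density of points spread over
a two-dimensional cap grows linearly at short range). The per-image
baseline slope $k_0$ (counts per Å⁻¹, i.e. Å) is therefore fitted by
ordinary least squares over *baseline regions*, and normalised into

$$K = \frac{k_0}{(N/S)\,N} = \frac{k_0 S}{N^2} \quad (\text{Å}^{-1}),$$

where $S = 2\pi\lambda^{-2}(1 - \cos 2\theta_{\max})$ is the Ewald-cap area
containing the spots. Images with $K > 1.4\times10^{-4}$ Å⁻¹ — the level at
which a satellite lattice contributes about one third of the main lattice's
spots — are flagged as multi-pattern. `calibration_curve_k()` reproduces
this calibration: mean K rises monotonically with the satellite spot ratio
and is statistically indistinguishable from zero for a single lattice.

**Baseline regions.** Intra-lattice DDV peak positions are lattice-vector
*lengths*, identical for every image of a crystal regardless of
orientation, so baseline regions are determined once from the mesh-wide
cumulative histogram and reused for every per-image fit. Minima are located
with AMPD (automatic multiscale-based peak detection): the negated,
linearly detrended signal is scanned over window scales
$k = 1..\lceil n/2\rceil - 1$; the scale λ minimising the count of
non-extrema is selected (ties to the smallest scale, and a small
scale-relative tolerance keeps round-off from fabricating extrema on flat
or linear signals); indices that are extrema at every scale up to λ are
returned. AMPD's edge exclusion means extrema within λ bins of either end
are not reported — acceptable here, where the informative minima are
interior. Three refinements stabilise the subsequent per-image fits:

* minima whose cumulative count exceeds the lower quartile plus 1% of the
  dynamic range are discarded — they are dips inside the quasi-continuum of
  closely spaced high-order lattice distances and still carry lattice
  counts;
* every bin with **zero** cumulative count is added: a bin empty across the
  entire mesh provably contains no intra-lattice distance of any crystal
  present;
* one guard bin is trimmed from each side of every baseline run longer than
  two bins, because measured peak tails (spot-centroid error) bleed into
  the adjacent bin and would otherwise bias $k_0$ upward for strongly
  diffracting orientations.

Nodes with fewer than `min_spots_for_k` (default 10) spots, or with fewer
than three usable baseline bins in the fit range
$(1\text{–}40)\times10^{-3}$ Å⁻¹, are treated as single-pattern (the slope
of a near-empty histogram is noise).

## Crystal discrimination

Diffracting nodes (score strictly above `score_floor`, default 0) that are
not flagged multi-pattern are partitioned into 8-connected components;
diagonal adjacency counts because visually marginal connectivity is common
in real maps (4-connectivity is available via `connectivity = 4`). Within
each region every node pair receives the distance score

$$D = \Bigl(\tfrac1N \sum_{i=1}^{N} \Delta_i^2\Bigr)^{1/2},$$

where the image with fewer spots is the reference (ties: first argument,
for determinism), and $\Delta_i$ is the angle between reference spot *i*'s
scattered ray and the nearest ray of the compared image if below the 0.1°
gate, else 0.1°. The gate reflects the ~3×3-pixel integration footprint of
upstream spot finders; D is bounded by it and independent of the spot-list
sizes. Nearest rays are found by exact maximum cosine over the dense Gram
matrix — at mesh-scale spot counts (hundreds) this is faster in practice
than an index structure and has no approximation error. One-to-one matching
is deliberately **not** enforced: the score is defined per reference spot.
For two unrelated lattices nearly every $\Delta_i$ is capped, so D sits
just below 0.1° (the deficit is the random-coincidence rate); the cutoff
0.093° separates same-crystal from different-crystal pairs.

Clustering uses agglomerative **ω-gated weighted average linkage**: the
distance between clusters is the mean of cross-pair D values with weight 0
for pairs more than `omega_gate` = 0.5° apart in ω and weight 1 otherwise.
The gate removes exactly those pairs whose D is saturated by ω distance
rather than by crystal identity. If every cross pair of two clusters is
gated out, their distance falls back to the gate value 0.1° — a
conservative choice (the method leaves this case open) that prevents
merging clusters about which nothing is known. Merge ties break towards the
smallest cluster indices; with all weights 1 the procedure reduces exactly
to textbook average linkage, which the test suite verifies against
`stats::hclust` on random matrices. The dendrogram is cut by applying every
merge with linkage distance strictly below `d_cutoff` = 0.093°. This
machinery reproduces the qualitative behaviour expected of real scans: a
smooth lattice-orientation bend of ~1° across a crystal chains together
into a single crystal, while an abrupt 1° step splits into two; a satellite
misoriented by a few degrees on top of a large crystal separates into its
own cluster, with the superposition zone flagged grey.

The custom linkage is implemented directly (naive O(n³)); mesh regions are
at most a few hundred nodes, and no off-the-shelf linkage accepts pairwise
weight masks.

## Shape fitting and ranking

Each crystal's score diagram is approximated by a semi-ellipsoid

$$E(x,y) = H\sqrt{\max\!\bigl(0,\,1 - u^2/a^2 - v^2/b^2\bigr)},$$

with $(u,v)$ the in-plane coordinates rotated by φ about the centre
$(x_0, y_0)$; mesh coordinates are x = column, y = row. The fit minimises
$\sum_i \alpha_i\,(E(x_i,y_i) - s_i)^2$ over the crystal's own nodes
(weight 1) plus the no-diffraction nodes of the crystal's bounding box
dilated by 2 nodes (target 0, weight `penalty_weight` = 10), excluding
nodes of other crystals and multi-pattern zones. The penalty keeps fitted
volume from hanging over provably empty mesh area; binary weights are the
simplest form consistent with the method's description. Six parameters are
optimised (H, x₀, y₀, a, b, φ) — descriptions of the approach sometimes
speak of five, but all six are needed for an anisotropic tilted footprint.

Optimisation is classic differential evolution (rand/1/bin, population 45,
150 generations, F = 0.7, CR = 0.9) over documented box bounds (centre in
the dilated bounding box; a, b in (0.3, max grid dimension); H in
(0, 2·max score]; φ ∈ [0°, 180°)), followed by an L-BFGS-B polish of the
best member within the same bounds — mirroring common practice for this
optimiser family. The DE seed is `de_seed + crystal_id`, so fits are
independent yet fully reproducible, and the per-generation best-so-far
trace is monotone by construction (asserted in tests). Fits are
canonicalised to a ≥ b with φ reduced modulo 180°, which collapses the
(a, b, φ) ↔ (b, a, φ+90°) degeneracy. A single-node crystal is a degenerate
but legal input: the height fits the node's score and the axes rest near
the sub-node lower bound 0.3. Should the optimiser ever return a
non-finite parameter vector, the crystal is reported with bounding-box
fallback dimensions and flagged.

Crystals are ranked by the integral diffraction signal
$I = \tfrac23\pi a b H$, descending, with ties broken by crystal id. The
crystal map labels nodes −2 (multi-pattern), 0 (no signal) or by crystal
id, and the renderer cycles a fixed nine-colour palette (any fixed palette
serves; nine colours keep neighbouring crystals visually distinct) tinted
by score, with grey multi-pattern zones and fitted ellipse outlines.

## The simulator: what it emulates, and what it does not

`simulate_mesh()` provides ground-truth test data. Each crystal occupies an
elliptical footprint; its score surface is exactly the semi-ellipsoid of
its specification (no score noise), emulating a diffraction strength
proportional to illuminated crystal thickness. Every covered node receives
the crystal's still-image spot pattern: reciprocal nodes within the
resolution sphere diffract when their angular offset from the Ewald sphere
(radius 1/λ, through the origin) is below `excitation_halfwidth`, and are
projected along the scattered ray onto the detector. Defaults are chosen
as typical cryo-MX conditions: λ = 1 Å, 250 mm detector distance,
0.172 mm pixels on a 1475×1679 pixel-array detector, a 68×72×78 Å
orthorhombic protein cell, 2.0 Å resolution limit, ω increment 0.05° per
image — together giving a few hundred spots per image. The excitation
half-width default of 0.1° represents the effective still-image reflection
width (mosaicity + bandwidth + divergence) of a decent cryocooled protein
crystal. Spot centroids carry Gaussian jitter (`centroid_sigma_px`,
default 0.3 px), emulating centroiding error — this is what gives the
distance score its random error floor and the DDV peaks their finite
width. Optional uniform noise spots (default 0: upstream spot lists are
assumed cleaned) exercise robustness of the capped D score and of K.
Superposed crystals contribute the exact union of their spot lists, and a
nonzero `orientation_gradient` rotates the lattice about the goniometer
axis in proportion to the node's position along the footprint's major
axis (a gradually bent crystal).

Not emulated: physical intensities, partiality, polarisation, absorption,
detector point-spread, salt/ice rings, and any dependence of the spot
*count* on the illuminated volume (edge nodes of a crystal show the full
pattern at reduced score). Passing tests therefore demonstrate the
geometric and statistical machinery — lattice superposition statistics,
ray similarity, clustering, shape recovery — not detector physics.
Satellite spot ratios in `calibration_curve_k()` are enforced by random
subsampling of the satellite's spot list, which matches the ratio's
definition without modelling crystal volume.

## Problem sizes and runtime choices

The test suite runs simulations at desk scale, chosen to exercise every
code path while keeping the full suite in the low minutes: grids of
9×9–11×11 nodes, regions of up to ~40 nodes (with a 30-node/435-pair
condensed-matrix replica of a large homogeneous-crystal region), 200
simulated image pairs for the null level of D, 50 replicates per satellite
ratio for the K calibration, 20 randomised crystals for shape-parameter
recovery and 20 seeded scans for end-to-end crystal-count recovery.
Reciprocal-lattice candidate sets are enumerated once per (cell,
resolution) and cached, so a still image simulates in tens of
milliseconds.

## Known limitations

* A crystal split across disconnected regions is reported as two crystals;
  regions are never merged.
* The binary multi-pattern flag does not distinguish two superposed
  lattices from many.
* The dendrogram cutoff is fixed (0.093°); no automatic cutoff selection.
* K's absolute scale depends on spot density homogeneity across the cap;
  strongly anisotropic diffraction could shift the effective threshold.
* The per-row ω convention is an assumption about acquisition order; scans
  acquired in a genuinely monotone or serpentine order need their bundle
  written with the matching `omega_start`/`omega_per_image` so that node ω
  values are correct, since all gating derives from them.
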