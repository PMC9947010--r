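---
title: "Methods: mobility decomposition, tessellation clustering and co-localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mobility decomposition, tessellation clustering and co-localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models behind `smlmtools`, the defaults and why
they were chosen, the numerical decisions, and what a green test on
synthetic data does and does not establish.

## 1. Mobility model and the MJD statistic

A membrane protein imaged by TIRF single-particle tracking is modelled as a
two-dimensional Brownian walker: per frame interval `dt` each coordinate
takes a Gaussian step of SD `sqrt(2 D dt)`, and each observed position
carries independent per-axis localization noise of SD `sigma`. The **mean
jump distance** (MJD) of a track is the average Euclidean displacement
between *consecutive* frames; pairs spanning detection gaps are excluded so
that blinking does not inflate apparent jumps. The MJD needs no a-priori
diffusion model, which is why it is preferred over MSD fitting here.

Under this model the jump between two observed positions is Rayleigh with
per-axis SD `sqrt(2 D dt + 2 sigma^2)`, so the expected jump is

```
E[jump] = sqrt(pi * (D * dt + sigma^2))
```

This closed form is the package's principal oracle: it fixes the diffusion
coefficients used in the simulations (`D = 0.111` and `0.293 um^2/s` at
`dt = 1/33 s`, `sigma = 24.8 nm` reproduce low/high component means of
111.8 and 172.7 nm; `D = 0` with `sigma = 24.82 nm` gives the 44 nm
immobile reference) and it is what the acceptance suite checks the
simulator and estimator against, over a grid of `(D, sigma)`.

Population decomposition follows the common curve-fitting workflow: per-track
MJDs are histogrammed (default 10 nm bins over 0–400 nm; an overflow bin
conserves counts) and the counts are least-squares fitted with a sum of two
Gaussians. Component areas are `A * s * sqrt(2*pi)` and the high-mobility
fraction is `R = area_high / (area_low + area_high)`. A sample-level EM fit
(`fit_two_gaussians_em()`) is provided as an independent cross-check; the two
routes agree on simulated mixtures. Tracks are classified low/high at
140 nm; the boundary value itself goes to "high" (the convention must pick a
side; tests pin it).

**Numerical choices.** The least-squares fit runs L-BFGS-B on
`(A1, mu1, log s1, A2, mu2, log s2)` (log-SD keeps scales positive), is
initialised from the moments of the sub-samples below/above the 140 nm
threshold, and restarts from deterministically perturbed starting points
(up to 5) keeping the best converged optimum. A fit is flagged *degenerate*
when a component carries < 1% of the total area **or** when the means are
closer than half the summed SDs — single-population data otherwise split
into two overlapping halves that a pure area criterion does not catch.
`r_value()` refuses degenerate fits unless forced.

**Track linking.** The reference linker in this field is closed-source, so
linking is a deterministic greedy nearest-neighbour assignment:
frame-by-frame, candidate (localization, open end) pairs are accepted in
ascending distance, ties broken by lower localization id then lower track
id, rejecting pairs beyond `max_link_distance`. At the emitter separations
the simulations use (≥ 5x the typical jump) ground-truth link purity
exceeds 99%, which is sufficient for MJD statistics; dense acquisitions
would need a motion-model linker and are out of scope.

## 2. Localization post-processing

* **Sigma filter**: localizations with Gaussian-fit SD > 200 nm are
  out-of-focus and removed (`filter_sigma`, inclusive at the cutoff).
* **Grouping**: emissions of one emitter in consecutive frames (gap
  configurable, unbounded by default — "trace length infinite") within one
  camera pixel of the chain's running centroid are merged to the unweighted
  centroid, first-frame timestamp, summed intensity. The pixel defaults to
  **160 nm** (16 um EMCCD pixel / 100x objective); the instrument pixel is
  configurable because the true value is instrument-specific.
* **Drift**: fiducial-based estimation averages per-fiducial trajectories
  (linearly interpolated across missing frames, 10-frame moving average,
  zero at the reference frame). The cross-correlation fallback renders
  temporal segments as 2D histograms (20 nm pixels), reads each segment's
  shift against the first from the FFT cross-correlation peak with
  per-axis parabolic sub-pixel refinement, and interpolates linearly
  between segment midpoints (linear extrapolation beyond the first/last
  midpoint). The correlation plane is Gaussian-smoothed (2 px) because
  sparse renderings otherwise give a broad noisy peak that defeats
  sub-pixel refinement. A result is flagged `low_confidence` when the mean
  peak z-score falls below 15: featureless (CSR) planes score at the
  extreme-value level of noise (~7–9), structured images an order of
  magnitude higher.
* **Chromatic registration**: channel B first inherits channel A's drift
  model (sequential acquisition), then an affine map fitted by least
  squares on ≥ 3 non-collinear matched bead positions corrects chromatic
  aberration. Recovery is exact (≤ 1e-9) on noise-free pairs.
* **FRC**: the table is split (even/odd frames by default — appropriate for
  blinking data since each emitter contributes to both halves — or random
  halves), each half rendered at 10 nm, and the per-ring correlation of the
  Fourier transforms is smoothed with a 3-bin moving average before reading
  the first crossing of the fixed 1/7 threshold; the crossing frequency is
  interpolated within the bin. A curve that never crosses is reported as
  unresolved (`Inf`).

## 3. Voronoï density, segmentation, co-localization

Per localization, the **first-rank density** is
`delta_i = (N_i + 1) / (area of cell i + areas of its N_i edge-adjacent
cells)`; `delta` is its mean over interior points. Convex-hull points own
unbounded cells: they are flagged, excluded from `delta` and can never be
"dense". Cocircular configurations (exact lattices) give Voronoï edges of
zero length; these degenerate contacts are dropped from adjacency, which is
what makes the square-lattice check exact (`delta_i = 1/a^2`, 4
neighbours). Plain `1/area` density is available as an option.

**Segmentation** thresholds at `density_factor` (fixed at 1.0, following
the source workflow) times `delta` and takes connected components of dense
points under Voronoï adjacency, discarding components below `min_locs`
(default 25). Cluster area is the sum of member cell areas; the diameter is
the equivalent-circle value `2*sqrt(area/pi)` (max-Feret would
overestimate elongated clusters' size relative to the reported convention).

Two properties of the `1x delta` threshold are worth understanding before
interpreting results:

* The threshold is only meaningful when a diffuse background sets the
  reference density. A lone densely sampled disk has `delta` close to the
  disk's own density, so the threshold always erodes the rim (the
  equivalent diameter of an isolated 400 nm disk comes out near 280 nm).
  With a realistic diffuse membrane background (tens of localizations per
  um^2, as in the simulated scenes) clusters are recovered whole and
  diameters land within ~15% of truth, the residual deficit being rim
  cells whose neighbourhood dips below threshold.
* On pure CSR the dense fraction at `1x delta` is ~49% — essentially the
  site-percolation threshold of a Delaunay graph — so CSR realizations
  routinely contain connected dense components of ≥ 25 points (1–6 per
  1000-point field measured over 20 seeds). Zero false clusters on CSR is
  *not* a property of this procedure at factor 1.0; raising the factor to
  2 suppresses them. The acceptance suite keeps the specified factor-1.0
  check and documents its failure rather than silently switching factors.

**Spearman co-localization** pairs, for every localization position of
either channel, the first-rank densities of the two channels' cells
containing that position (nearest-cell lookup); the statistic is the rank
correlation with mid-ranked ties, reported pooled and per channel (the
underlying tools disagree on which variant they print, so all are
exposed). Pairs whose cell in either channel touches the tessellation
border (the hull, or adjacent to it) are excluded: both channels share a
low-density rim there, and that common gradient alone correlates even
independent patterns (measured ρ ≈ 0.15 for unrelated CSR channels at
5000 points without the exclusion, ≈ 0.05 with it).

**Manders coefficients**: `M_A` is the fraction of channel-A localizations
whose containing channel-B cell is dense at `1x` B's mean density, and
symmetrically for `M_B`. Identical channels give `M_A == M_B` exactly.

**Controls** mirror standard practice: the positive control splits one
acquisition by frame parity (same structure, independent emissions → high
ρ); the negative control flips the localizations vertically about the
bounding-box midline (an involution, so applying it twice restores the
input).

## 4. Synthetic data: what it emulates, and what it does not

`simulate_tracks` draws per-track populations, reflects true positions at
the field edges (reflection avoids the density depletion that absorbing or
wrapping edges would create; the default 40.96 um field is a 256-pixel
EMCCD region at 160 nm/px, so edge contacts are rare), and adds per-axis
Gaussian noise. Frames are integers `0..N-1`; physical time is
`frame * dt` with `dt = 1/33 s` by default.

`simulate_clustered_points` places disk clusters uniformly (fully inside
the field), members uniform within the disk, a CSR background at a stated
density, and gives each emitter `1 + Poisson(blinks)` localizations on
uniformly random frames, each jittered by the localization precision. This
is the simplest blinking model that produces the multi-count clustering the
grouping step must collapse; it deliberately has **no** photophysical dwell
times, no camera-frame rendering (PSF, EMCCD noise) and no 3D. Two-channel
scenes derive channel B from A as:

* `coclustered` — fresh localizations re-sampled from the *same* emitters
  (same nanostructure, independent noise);
* `independent` — a spatially unrelated CSR channel with matched count.
  A fresh clustered realization would be the literal reading of
  "independent", but it is distributionally indistinguishable from the
  flipped negative control (both are clustered patterns unrelated to A),
  so it cannot sit *between* the co-clustered and mirrored cases; CSR is
  the natural "no spatial relation" null and is what the ordering
  property `rho(coclustered) > rho(independent) > rho(mirrored)` assumes;
* `mirrored` — the vertical flip of A itself (the classical negative
  control);

followed by an affine chromatic transform.

Consequently, a green test establishes that the estimators recover the
parameters of *this* stated world — Brownian mixtures, disk clusters,
linear drift, affine chromatics — at the stated sizes and noise levels. It
does not establish robustness to anomalous diffusion, emitter
photophysics, non-affine aberrations, or labelling-density artifacts.

## 5. Degenerate inputs and tolerances

* Exact duplicate coordinates are nudged deterministically by ~1e-9 of the
  field before tessellating (a zero-area cell is otherwise undefined).
* Fewer than 4 points, or collinear points, refuse to tessellate.
* Drift models must cover every frame they are asked about; the reference
  frame has zero displacement by construction.
* Round-trips (drift apply/correct, CSV write/read, double flip) are exact
  to ≤ 1e-9 nm and tested as such.
* The incremental Delaunay uses Shewchuk-style error-bounded sign
  predicates; numerically cocircular points are merged into the insertion
  cavity, which keeps exact lattices valid without symbolic perturbation.
  Cell areas agree with an independent computational-geometry
  implementation to ~1e-9 relative on random fields.

## 6. Known limitations

* Greedy linking has no gap-closing cost model; it is adequate at the
  simulated densities only.
* The per-track MJD histogram fit inherits the histogram's bin choice;
  R is stable within 0.02 across 5–20 nm bins on the standard simulation,
  but pathological binning is not defended against.
* FRC on very sparse tables is noisy; the 2000-localization floor is a
  guard, not a guarantee.
* The `1x delta` segmentation threshold behaves as discussed in §3 on
  background-free or CSR-only data.
* Foci detection implements the prominence ("noise tolerance") semantics
  of the common find-maxima tool with plateau ties broken at the lowest
  pixel index; it is intended for maximum projections, not z-stacks.
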