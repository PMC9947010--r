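# smlmtools

Tools for quantifying the nanoscale organization and mobility of
cell-surface molecules from single-molecule localization microscopy
(SMLM/STORM) and single-particle tracking (SPT) data — the kind of analysis
used to ask how "eat-me" / "don't eat-me" ligands such as calreticulin and
CD47 redistribute and diffuse on the plasma membrane.

The package covers four stages that normally live in separate ImageJ
plugins, as one tested R pipeline:

1. **Localization post-processing** (`loc_table`): ThunderSTORM-dialect CSV
   I/O, sigma filtering (fit SD ≤ 200 nm), grouping of consecutive-frame
   emissions, fiducial- and cross-correlation drift correction, two-channel
   registration, affine chromatic-aberration correction, Fourier ring
   correlation (FRC) resolution.
2. **Mobility analysis**: greedy deterministic track linking, per-track
   **mean jump distance** MJD = mean distance travelled between consecutive
   frames, two-Gaussian decomposition of the MJD histogram

   `N(x) = A_low g(x; mu_low, s_low) + A_high g(x; mu_high, s_high)`

   and the high-mobility area fraction (**R-value**)

   `R = A_high s_high / (A_low s_low + A_high s_high)`

   with a 140 nm low/high classification threshold. For Brownian motion
   observed with per-axis localization noise sigma the expected jump is the
   closed form `sqrt(pi (D dt + sigma^2))`, which calibrates and validates
   the simulations.
3. **Voronoï tessellation analysis**: per-localization first-rank density
   `delta_i = (N_i + 1) / (area of cell i + its N_i neighbour cells)`,
   cluster segmentation at a `1x` mean-density threshold with
   equivalent-circle diameters, and coordinate-based co-localization:
   Spearman rank correlation of paired per-position densities, Manders
   coefficients against the partner channel's dense region, even/odd-frame
   positive and vertical-flip negative controls.
4. **Quantifications**: find-maxima foci detection with noise tolerance,
   foci density per cell area, and the phagocytic index
   `(p_cond − p_cond,CytD) / (p_ctrl − p_ctrl,CytD)`.

A first-class synthetic-data module simulates Brownian track populations,
blinking clustered emitters over CSR background, stage drift, fiducial
markers and derived second channels with full ground truth, so every stage
is testable without microscope data. The Delaunay/Voronoï engine is
implemented in C++ (Rcpp) and validated against an independent
computational-geometry oracle.

## Worked example

```r
library(smlmtools)

# a TIRF SPT acquisition at 33 Hz: two diffusion populations (2/3 slow at
# D = 0.111 um^2/s, 1/3 fast at 0.293 um^2/s), 24.8 nm localization noise
cfg <- sim_track_config(n_tracks = 5000, track_length = 50,
                        populations = list(c(D = 0.111, weight = 2/3),
                                           c(D = 0.293, weight = 1/3)),
                        loc_precision = 24.8, seed = 1)
sim  <- simulate_tracks(cfg)
mjds <- track_mjds(sim$tracks)
fit  <- fit_two_gaussians(mjds)
print(fit)
#> <two_gauss_fit> mu_low=111.8 nm (s=8.7), mu_high=172.0 nm (s=13.1)
#>   R = 0.338 (high-mobility area fraction)
lab <- classify_tracks(mjds)          # 140 nm threshold
#> high-mobility tracks: 33.6%
```

The fitted component means land on the closed-form values
`sqrt(pi (D/33 + sigma^2))` = 111.8 and 172.7 nm, and R recovers the
simulated fast-population weight 1/3.

```r
# STORM-style clustered channel: two 200-nm disks over diffuse background
sim2 <- simulate_clustered_points(sim_cluster_config(
  n_clusters = 2, cluster_radius = 200, locs_per_cluster = 500,
  background_density = 20, loc_precision = 5, field_size = 10000, seed = 5))
segment_clusters(sim2$table)
#> <cluster_set> 2 cluster(s), 817 dense / 2980 points
#>   cluster n_locs     area diameter
#> 1       1    413 100333.3 357.4190
#> 2       2    404 101938.3 360.2663
```

Both disks are recovered; the equivalent-circle diameters
(`2 sqrt(area/pi)`) sit within 15% of the true 400 nm (the rim cells whose
Voronoï neighbourhood dips below the 1x mean-density threshold are
excluded, a known property of this segmentation).

## Command line

```sh
Rscript inst/exec/smlmtools simulate clusters --n-clusters 20 --seed 1 --out locs.csv
Rscript inst/exec/smlmtools process filter-sigma --in locs.csv --out kept.csv
Rscript inst/exec/smlmtools tessellate segment --in kept.csv --out clusters.csv
```

See `vignettes/methods.Rmd` for the model assumptions, parameter defaults,
numerical choices and the limits of what the synthetic data can establish.
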