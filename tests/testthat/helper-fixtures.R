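# Shared fixtures built in code (no data files).

# closed-form expected mean jump distance for Brownian motion plus
# localization noise: sqrt(pi * (D * dt + sigma^2)), D in um^2/s, sigma nm
expected_mjd <- function(D, sigma, dt = 1 / 33) {
  sqrt(pi * (D * 1e6 * dt + sigma^2))
}

# a small deterministic CSR table
csr_table <- function(n, field = 10000, seed = 1, n_frames = 100) {
  withr::with_seed(seed, {
    loc_table(frame = seq_len(n) %% n_frames,
              x = stats::runif(n) * field,
              y = stats::runif(n) * field)
  })
}

# standard two-population SPT simulation used across mobility tests
standard_spt <- function(n_tracks = 5000, seed = 101) {
  simulate_tracks(sim_track_config(
    n_tracks = n_tracks, track_length = 50,
    populations = list(c(D = 0.111, weight = 2 / 3),
                       c(D = 0.293, weight = 1 / 3)),
    loc_precision = 24.8, seed = seed))
}

# standard clustered two-channel scene for co-localization tests
standard_clusters <- function(seed = 21, n_clusters = 25,
                              locs_per_cluster = 160) {
  simulate_clustered_points(sim_cluster_config(
    n_clusters = n_clusters, cluster_radius = 150,
    locs_per_cluster = locs_per_cluster, background_density = 10,
    loc_precision = 10, field_size = 10000, n_frames = 5000, seed = seed))
}
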