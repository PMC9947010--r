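test_that("track simulation matches the closed-form mean jump distance", {
  # immobile emitters: mean MJD = sigma * sqrt(pi)
  sim0 <- simulate_tracks(sim_track_config(
    n_tracks = 2000, track_length = 50,
    populations = list(c(D = 0, weight = 1)),
    loc_precision = 24.82, seed = 7))
  m0 <- track_mjds(sim0$tracks)
  expect_equal(mean(m0), 24.82 * sqrt(pi), tolerance = 1 / 44)

  # single mobile population within 2% of sqrt(pi (D dt + sigma^2))
  sim1 <- simulate_tracks(sim_track_config(
    n_tracks = 2000, track_length = 50,
    populations = list(c(D = 0.111, weight = 1)),
    loc_precision = 24.8, seed = 8))
  expect_equal(mean(track_mjds(sim1$tracks)),
               expected_mjd(0.111, 24.8), tolerance = 0.02)
})

test_that("simulation is seed-deterministic and validates configs", {
  cfg <- sim_track_config(n_tracks = 50, track_length = 20, seed = 11)
  a <- simulate_tracks(cfg)
  b <- simulate_tracks(cfg)
  expect_identical(a$table$x, b$table$x)
  expect_identical(a$population, b$population)
  c_ <- simulate_tracks(sim_track_config(n_tracks = 50, track_length = 20,
                                         seed = 12))
  expect_false(identical(a$table$x, c_$table$x))

  expect_error(sim_track_config(populations = list(c(D = 1, weight = 0.5))),
               "sum to 1")
  expect_error(sim_track_config(n_tracks = 0), "positive")
  expect_error(sim_track_config(field_size = -1), "field")
  expect_error(sim_track_config(frame_interval = 0), "frame_interval")
})

test_that("tracks stay in the field and frames increase by 1", {
  sim <- simulate_tracks(sim_track_config(
    n_tracks = 30, track_length = 40, field_size = 2000,
    populations = list(c(D = 0.5, weight = 1)), loc_precision = 0,
    seed = 13))
  by_track <- split(sim$tracks$frame, sim$tracks$track_id)
  expect_true(all(vapply(by_track, function(f) all(diff(f) == 1),
                         logical(1))))
  # true positions reflect at the walls; only localization noise may leak
  expect_true(all(sim$tracks$x >= 0 & sim$tracks$x <= 2000))
})

test_that("clustered-point generator conserves counts and blinking", {
  cfg <- sim_cluster_config(n_clusters = 0, cluster_radius = 100,
                            locs_per_cluster = 0, background_density = 1,
                            blinks_per_emitter = 0,
                            field_size = 10000, seed = 14)
  sim <- simulate_clustered_points(cfg)
  # ~100 CSR localizations at 1 per um^2 over 100 um^2; one per emitter
  expect_equal(nrow(sim$table), nrow(sim$truth))
  expect_gt(nrow(sim$table), 60)
  expect_lt(nrow(sim$table), 140)

  cfg2 <- sim_cluster_config(n_clusters = 4, cluster_radius = 100,
                             locs_per_cluster = 100,
                             background_density = 0,
                             blinks_per_emitter = 4, seed = 15)
  sim2 <- simulate_clustered_points(cfg2)
  expect_equal(nrow(sim2$truth), 400)
  # Poisson(4) + 1 blinks: ~5 localizations per emitter
  expect_equal(nrow(sim2$table) / nrow(sim2$truth), 5, tolerance = 0.1)
  # every localization maps to exactly one emitter
  expect_true(all(sim2$table$emitter %in% sim2$truth$emitter))
  # cluster members lie inside their disk (up to localization jitter)
  d <- sqrt((sim2$truth$x - sim2$centers$x[sim2$truth$cluster])^2 +
            (sim2$truth$y - sim2$centers$y[sim2$truth$cluster])^2)
  expect_true(all(d <= 100 + 1e-9))
  expect_error(sim_cluster_config(cluster_radius = 6000,
                                  field_size = 10000), "diameter")
})

test_that("two-channel derivation behaves per mode", {
  sim <- standard_clusters(seed = 16, n_clusters = 10,
                           locs_per_cluster = 50)
  tr <- affine_transform(matrix(c(1.001, 0, 0, 0.999), 2, 2), c(20, -10))
  cc <- make_two_channel(sim$table, truth = sim$truth, transform = tr,
                         mode = "coclustered", loc_precision = 10,
                         seed = 17)
  expect_equal(unique(cc$B$channel), 2L)
  # mirrored mode is exactly the vertical flip through the transform
  mi <- make_two_channel(sim$table, mode = "mirrored",
                         field_size = 10000)
  expect_equal(sort(10000 - mi$B$y), sort(sim$table$y))
  ind <- make_two_channel(sim$table, mode = "independent",
                          field_size = 10000, seed = 18)
  expect_equal(nrow(ind$B), nrow(sim$table))
  expect_error(make_two_channel(sim$table, mode = "coclustered"),
               "truth")
})

test_that("fiducials are added with the advertised structure", {
  tab <- csr_table(200, seed = 19, n_frames = 1000)
  none <- add_fiducials(tab, n = 0)
  expect_identical(none$table, tab)
  fid <- add_fiducials(tab, n = 3, n_frames = 1000, seed = 20)
  expect_equal(nrow(fid$table), nrow(tab) + 3000)
  expect_equal(lengths(fid$fiducial_ids), c(`1` = 1000L, `2` = 1000L,
                                            `3` = 1000L))
  # with drift applied, a fiducial trajectory traces the drift
  truth <- drift_model(0:999, dx = 0.05 * (0:999), dy = rep(0, 1000))
  drifted <- apply_drift(fid$table, truth)
  f1 <- drifted[drifted$id %in% fid$fiducial_ids[[1]], ]
  slope <- stats::coef(stats::lm(f1$x ~ f1$frame))[2]
  expect_equal(unname(slope), 0.05, tolerance = 0.05)
})
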