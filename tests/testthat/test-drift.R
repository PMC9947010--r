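test_that("drift apply/correct round-trip and basic arithmetic", {
  tab <- csr_table(500, n_frames = 2001)
  dm <- drift_model(0:2000, dx = 0.025 * (0:2000), dy = rep(0, 2001))
  # linear drift 0.025 nm/frame: shift at frame 2000 is 50 nm
  one <- loc_table(frame = 2000, x = 0, y = 0)
  expect_equal(apply_drift(one, dm)$x, 50)
  # zero drift is the identity
  zero <- drift_model(0:2000, dx = rep(0, 2001), dy = rep(0, 2001))
  expect_equal(apply_drift(tab, zero)$x, tab$x)
  # round-trip to 1e-9 nm
  rt <- correct_drift(apply_drift(tab, dm), dm)
  expect_equal(rt$x, tab$x, tolerance = 1e-12)
  expect_equal(rt$y, tab$y, tolerance = 1e-12)
  # uncovered frame errors
  expect_error(apply_drift(loc_table(frame = 3000, x = 0, y = 0), dm),
               "cover")
  # register_second_channel is correct_drift on channel B
  tabB <- loc_table(frame = 100, x = 10, y = 20, channel = 2)
  expect_equal(register_second_channel(tabB, dm)$x, 10 - 0.025 * 100)
})

test_that("drift model invariants and CSV round-trip", {
  dm <- drift_model(0:10, dx = 5 + (0:10), dy = -2 - (0:10), reference = 0)
  expect_equal(dm$dx[1], 0)   # zero at the reference frame
  expect_equal(dm$dy[1], 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_drift(dm, path)
  back <- read_drift(path)
  expect_equal(back$dx, dm$dx)
  expect_error(drift_model(0:5, dx = rep(0, 6), dy = rep(0, 6),
                           reference = 99), "reference")
})

test_that("fiducial drift estimation recovers a linear drift", {
  n_frames <- 2000
  sim <- standard_clusters(seed = 3)
  tab <- sim$table
  tab <- tab[tab$frame < n_frames, , drop = FALSE]
  fid <- add_fiducials(as_loc_table(as.data.frame(tab)), n = 3,
                       loc_precision = 10, n_frames = n_frames,
                       field_size = c(10000, 10000), seed = 4)
  truth <- drift_model(0:(n_frames - 1), dx = 0.025 * (0:(n_frames - 1)),
                       dy = -0.015 * (0:(n_frames - 1)))
  drifted <- apply_drift(fid$table, truth)
  est <- estimate_drift_fiducials(drifted, fid$fiducial_ids,
                                  frames = 0:(n_frames - 1))
  rmse <- sqrt(mean((est$dx - truth$dx)^2 + (est$dy - truth$dy)^2))
  expect_lt(rmse, 5)
  expect_error(estimate_drift_fiducials(drifted, list()), "no fiducials")
})

test_that("averaging several fiducials beats a single one", {
  n_frames <- 1000
  base <- loc_table(frame = 0, x = 1, y = 1)
  fid <- add_fiducials(base, n = 4, loc_precision = 15,
                       n_frames = n_frames, field_size = c(1e4, 1e4),
                       seed = 8)
  truth <- drift_model(0:(n_frames - 1), dx = 0.05 * (0:(n_frames - 1)),
                       dy = rep(0, n_frames))
  drifted <- apply_drift(fid$table, truth)
  rmse_for <- function(ids) {
    est <- estimate_drift_fiducials(drifted, ids,
                                    frames = 0:(n_frames - 1))
    sqrt(mean((est$dx - truth$dx)^2 + (est$dy - truth$dy)^2))
  }
  expect_lt(rmse_for(fid$fiducial_ids), rmse_for(fid$fiducial_ids[1]))
})

test_that("cross-correlation drift: zero drift, recovery, CSR flag", {
  sim <- simulate_clustered_points(sim_cluster_config(
    n_clusters = 40, cluster_radius = 150, locs_per_cluster = 600,
    background_density = 20, loc_precision = 10, field_size = 10000,
    n_frames = 2000, seed = 3))
  # zero drift: all estimated shifts within half a rendering pixel
  est0 <- estimate_drift_xcorr(sim$table, segment_frames = 400,
                               render_pixel = 20, frames = 0:1999)
  expect_lt(max(abs(est0$dx), abs(est0$dy)), 10)
  # applied 50 nm linear drift: endpoint recovered within 10 nm
  truth <- drift_model(0:1999, dx = 0.025 * (0:1999),
                       dy = -0.015 * (0:1999))
  drifted <- apply_drift(sim$table, truth)
  est <- estimate_drift_xcorr(drifted, segment_frames = 200,
                              render_pixel = 20, frames = 0:1999)
  i <- 2000
  err <- sqrt((est$dx[i] - truth$dx[i])^2 + (est$dy[i] - truth$dy[i])^2)
  expect_lt(err, 10)
  expect_false(attr(est, "low_confidence"))
  # featureless CSR data are flagged
  csr <- csr_table(4000, seed = 9, n_frames = 2000)
  estc <- estimate_drift_xcorr(csr, segment_frames = 500, render_pixel = 20)
  expect_true(attr(estc, "low_confidence"))
  expect_error(estimate_drift_xcorr(csr, segment_frames = 5000), "segments")
})
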