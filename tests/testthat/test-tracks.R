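test_that("linking reconstructs simple constructed scenes", {
  # one emitter over 50 consecutive frames with tiny jumps: a single track
  withr::with_seed(1, {
    tab <- loc_table(frame = 0:49, x = cumsum(rnorm(50, 0, 5)) + 500,
                     y = cumsum(rnorm(50, 0, 5)) + 500)
  })
  ts <- link_tracks(tab, max_link_distance = 100)
  expect_equal(length(unique(ts$track_id)), 1L)
  expect_equal(nrow(ts), 50L)

  # two emitters always far apart: two tracks, no switches
  tab2 <- loc_table(frame = rep(0:19, 2),
                    x = c(rep(100, 20), rep(5000, 20)),
                    y = rep(100, 40))
  ts2 <- link_tracks(tab2, max_link_distance = 300)
  expect_equal(length(unique(ts2$track_id)), 2L)
  sizes <- table(ts2$track_id)
  expect_true(all(sizes == 20))
  expect_error(link_tracks(tab2, max_link_distance = -5), "non-negative")
})

test_that("equidistant candidates are resolved by the lower id", {
  tab <- loc_table(frame = c(0, 1, 1), x = c(0, 50, -50), y = c(0, 0, 0),
                   id = c(1L, 2L, 3L))
  ts <- link_tracks(tab, max_link_distance = 100)
  # localization id 2 wins the tie and joins the track started at id 1
  t1 <- ts$track_id[ts$loc_id == 1]
  expect_equal(ts$track_id[ts$loc_id == 2], t1)
  expect_false(ts$track_id[ts$loc_id == 3] == t1)
})

test_that("track filter keeps strictly more than 10 localizations", {
  ts <- data.frame(track_id = rep(1:3, times = c(10, 11, 3)),
                   frame = c(0:9, 0:10, 0:2),
                   x = 0, y = 0)
  class(ts) <- c("trackset", "data.frame")
  out <- filter_tracks(ts)
  expect_equal(unique(out$track_id), 2L)     # 11 kept, 10 and 3 removed
  expect_equal(attr(out, "n_kept"), 1L)
  expect_equal(attr(out, "n_removed"), 2L)
  empty <- filter_tracks(ts[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("compute_mjd follows the consecutive-frame definition", {
  tr <- data.frame(frame = 0:2, x = c(0, 100, 100), y = c(0, 0, 100))
  expect_equal(compute_mjd(tr), 100)
  static <- data.frame(frame = 0:4, x = rep(3, 5), y = rep(7, 5))
  expect_equal(compute_mjd(static), 0)
  # the pair spanning the 1->3 gap is excluded
  gap <- data.frame(frame = c(0, 1, 3), x = c(0, 60, 60), y = c(0, 0, 80))
  expect_equal(compute_mjd(gap), 60)
  expect_error(compute_mjd(data.frame(frame = c(0, 2), x = 1:2, y = 1:2)),
               "consecutive")
})

test_that("compute_mjd is translation- and rotation-invariant", {
  withr::with_seed(4, {
    tr <- data.frame(frame = 0:19, x = cumsum(rnorm(20, 0, 50)),
                     y = cumsum(rnorm(20, 0, 50)))
  })
  base <- compute_mjd(tr)
  shifted <- transform(tr, x = x + 1234, y = y - 987)
  expect_equal(compute_mjd(shifted), base)
  th <- 0.7
  rotated <- data.frame(frame = tr$frame,
                        x = cos(th) * tr$x - sin(th) * tr$y,
                        y = sin(th) * tr$x + cos(th) * tr$y)
  expect_equal(compute_mjd(rotated), base)
})

test_that("MJD histogram bins left-closed with overflow accounting", {
  h <- mjd_histogram(c(5, 15, 15), bin_width = 10)
  expect_equal(h$counts[1:2], c(1L, 2L))
  expect_equal(sum(h$counts) + h$overflow, h$n)
  h2 <- mjd_histogram(c(5, 500), bin_width = 10, range = c(0, 400))
  expect_equal(h2$overflow, 1L)
  expect_error(mjd_histogram(c(1, 2), bin_width = 0), "positive")
})

test_that("classification splits at 140 nm with the boundary in 'high'", {
  lab <- classify_tracks(c(100, 140, 200))
  expect_equal(as.character(lab), c("low", "high", "high"))
  expect_equal(attr(lab, "prop_high"), 2 / 3)
  expect_equal(length(classify_tracks(numeric(0))), 0L)
})

test_that("linking purity >= 99% on well-separated simulated emitters", {
  # 100 emitters on a jittered grid, random walks with steps << spacing
  withr::with_seed(6, {
    n_em <- 100; len <- 30
    gx <- rep(seq(1000, 19000, length.out = 10), 10)
    gy <- rep(seq(1000, 19000, length.out = 10), each = 10)
    x <- matrix(0, len, n_em); y <- matrix(0, len, n_em)
    x[1, ] <- gx; y[1, ] <- gy
    for (f in 2:len) {
      x[f, ] <- x[f - 1, ] + rnorm(n_em, 0, 20)
      y[f, ] <- y[f - 1, ] + rnorm(n_em, 0, 20)
    }
    tab <- loc_table(frame = rep(0:(len - 1), n_em),
                     x = as.numeric(x), y = as.numeric(y),
                     emitter = rep(seq_len(n_em), each = len))
  })
  ts <- link_tracks(tab, max_link_distance = 200)
  em_of <- tab$emitter[match(ts$loc_id, tab$id)]
  ord <- order(ts$track_id, ts$frame)
  same_track <- diff(ts$track_id[ord]) == 0
  link_ok <- diff(em_of[ord])[same_track] == 0
  expect_gte(mean(link_ok), 0.99)
})
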