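#' Per-frame stage drift model
#'
#' Holds the estimated (or ground-truth) lateral stage displacement for every
#' frame of an acquisition, relative to a reference frame where the
#' displacement is zero by construction.
#'
#' @param frames Integer frames the model covers (0-based, consecutive not
#'   required but every frame to be corrected must be present).
#' @param dx,dy Displacement in nm at each frame.
#' @param reference Reference frame index (default the first frame); the
#'   displacement there is forced to (0, 0) by subtracting its value.
#' @return An object of class `drift_model`.
#' @export
drift_model <- function(frames, dx, dy, reference = frames[1]) {
  stopifnot(length(frames) == length(dx), length(dx) == length(dy))
  ord <- order(frames)
  frames <- as.integer(frames[ord]); dx <- dx[ord]; dy <- dy[ord]
  if (anyDuplicated(frames)) stop("duplicate frames in drift model")
  iref <- match(as.integer(reference), frames)
  if (is.na(iref)) stop("reference frame not covered by the model")
  dx <- dx - dx[iref]; dy <- dy - dy[iref]
  structure(list(frames = frames, dx = dx, dy = dy,
                 reference = as.integer(reference)),
            class = "drift_model")
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf(
    "<drift_model> frames %d-%d (reference %d), endpoint shift (%.2f, %.2f) nm\n",
    min(x$frames), max(x$frames), x$reference,
    x$dx[length(x$dx)], x$dy[length(x$dy)]))
  invisible(x)
}

.drift_lookup <- function(drift, frames) {
  idx <- match(as.integer(frames), drift$frames)
  if (anyNA(idx)) {
    stop("drift model does not cover frame(s): ",
         paste(utils::head(unique(frames[is.na(idx)]), 5), collapse = ", "))
  }
  idx
}

#' Apply a drift model to a localization table
#'
#' Shifts every localization by the drift of its frame — the forward
#' (corrupting) direction used by the synthetic-data generator. The exact
#' inverse of [correct_drift()].
#'
#' @param table A `loc_table`.
#' @param drift A `drift_model` covering every frame present.
#' @return The shifted `loc_table`.
#' @export
apply_drift <- function(table, drift) {
  idx <- .drift_lookup(drift, table$frame)
  table$x <- table$x + drift$dx[idx]
  table$y <- table$y + drift$dy[idx]
  table
}

#' Correct stage drift in a localization table
#'
#' @inheritParams apply_drift
#' @return The corrected `loc_table`.
#' @export
correct_drift <- function(table, drift) {
  idx <- .drift_lookup(drift, table$frame)
  table$x <- table$x - drift$dx[idx]
  table$y <- table$y - drift$dy[idx]
  table
}

#' Register a sequentially acquired second channel
#'
#' Two-colour STORM acquisitions are sequential, so the drift trajectory
#' estimated on the first channel is applied to the second.
#'
#' @param tableB The channel-B `loc_table`.
#' @param driftA The `drift_model` estimated from channel A.
#' @return The corrected channel-B table.
#' @export
register_second_channel <- function(tableB, driftA) {
  correct_drift(tableB, driftA)
}

#' Estimate drift from fiducial markers
#'
#' Bright static emitters (gold nanoparticles) localized in most frames trace
#' the stage drift directly. Per fiducial, the trajectory relative to its
#' position at the reference frame is linearly interpolated across missing
#' frames; trajectories are averaged over fiducials and smoothed with a
#' moving average.
#'
#' @param table A `loc_table` containing the fiducial localizations (other
#'   localizations may be present; only rows whose `id` belongs to a
#'   fiducial are used). A `fiducial` id column produced by
#'   [add_fiducials()] is also honoured when `fiducial_ids` is a vector of
#'   fiducial labels.
#' @param fiducial_ids List of integer vectors (localization ids per
#'   fiducial), or a vector of labels matched against `table$fiducial`.
#' @param frames Frames the model must cover (default `0:max(frame)`).
#' @param smooth_window Moving-average window in frames (default 10).
#' @param reference Reference frame (default 0).
#' @return A `drift_model`.
#' @export
estimate_drift_fiducials <- function(table, fiducial_ids,
                                     frames = NULL, smooth_window = 10,
                                     reference = 0L) {
  if (is.null(frames)) frames <- 0:max(table$frame)
  if (!is.list(fiducial_ids)) {
    if (is.null(table$fiducial)) {
      stop("fiducial_ids must be a list of localization ids, or the table ",
           "must carry a 'fiducial' column")
    }
    fiducial_ids <- lapply(fiducial_ids, function(f) {
      table$id[!is.na(table$fiducial) & table$fiducial == f]
    })
  }
  if (length(fiducial_ids) == 0) stop("no fiducials supplied")
  nf <- length(frames)
  acc_x <- matrix(NA_real_, nrow = nf, ncol = length(fiducial_ids))
  acc_y <- acc_x
  for (k in seq_along(fiducial_ids)) {
    rows <- table[table$id %in% fiducial_ids[[k]], , drop = FALSE]
    if (nrow(rows) < 2) stop("fiducial ", k, " has fewer than 2 localizations")
    if (nrow(rows) < 0.5 * nf) {
      warning("fiducial ", k, " localized in < 50% of frames")
    }
    agg <- stats::aggregate(cbind(x, y) ~ frame, data = rows, FUN = mean)
    fx <- stats::approx(agg$frame, agg$x, xout = frames, rule = 2)$y
    fy <- stats::approx(agg$frame, agg$y, xout = frames, rule = 2)$y
    acc_x[, k] <- fx
    acc_y[, k] <- fy
  }
  dx <- rowMeans(acc_x); dy <- rowMeans(acc_y)
  dx <- .moving_average(dx, smooth_window)
  dy <- .moving_average(dy, smooth_window)
  drift_model(frames, dx, dy, reference = reference)
}

.moving_average <- function(v, window) {
  if (window <= 1) return(v)
  n <- length(v)
  half <- floor(window / 2)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Estimate drift by image cross-correlation
#'
#' For acquisitions without usable fiducials: the stack is cut into temporal
#' segments, each segment is rendered as a 2D localization histogram, and the
#' lateral shift of every segment against the first is read from the peak of
#' their cross-correlation (FFT-based, with 3x3 centroid sub-pixel
#' refinement). Per-frame drift is linearly interpolated between segment
#' midpoints.
#'
#' @param table A `loc_table` (single channel).
#' @param segment_frames Frames per temporal segment.
#' @param render_pixel Rendering pixel in nm (default 20).
#' @param frames Frames the model must cover (default `0:max(frame)`).
#' @param min_locs Minimum localizations per segment (default 100).
#' @param reference Reference frame (default 0).
#' @return A `drift_model` with attribute `peak_sharpness` (ratio of the
#'   correlation peak to the mean correlation) and `low_confidence` flag when
#'   the mean sharpness falls below 5 (featureless, e.g. pure CSR, data).
#' @export
estimate_drift_xcorr <- function(table, segment_frames, render_pixel = 20,
                                 frames = NULL, min_locs = 100,
                                 reference = 0L) {
  if (is.null(frames)) frames <- 0:max(table$frame)
  nseg <- ceiling((max(frames) + 1) / segment_frames)
  if (nseg < 2) stop("need at least 2 temporal segments")
  seg_of <- pmin(table$frame %/% segment_frames, nseg - 1)
  counts <- tabulate(seg_of + 1L, nbins = nseg)
  if (any(counts == 0)) stop("empty temporal segment")
  if (any(counts < min_locs)) {
    stop("segment(s) with fewer than ", min_locs, " localizations")
  }
  xr <- range(table$x); yr <- range(table$y)
  nx <- max(8L, ceiling(diff(xr) / render_pixel) + 1L)
  ny <- max(8L, ceiling(diff(yr) / render_pixel) + 1L)
  render <- function(rows) {
    .render_hist(rows$x, rows$y, xr[1], yr[1], render_pixel, nx, ny)
  }
  img0 <- render(table[seg_of == 0, , drop = FALSE])
  mids <- (seq_len(nseg) - 0.5) * segment_frames - 0.5
  sx <- numeric(nseg); sy <- numeric(nseg); sharp <- numeric(nseg)
  sharp[1] <- NA_real_
  for (k in seq_len(nseg - 1)) {
    imgk <- render(table[seg_of == k, , drop = FALSE])
    sh <- .xcorr_shift(img0, imgk)
    sx[k + 1] <- sh$dx * render_pixel
    sy[k + 1] <- sh$dy * render_pixel
    sharp[k + 1] <- sh$sharpness
  }
  interp <- function(v) {
    out <- stats::approx(mids, v, xout = frames, rule = 2)$y
    # linear extrapolation beyond the first/last segment midpoints
    m <- length(mids)
    lo <- frames < mids[1]
    hi <- frames > mids[m]
    if (any(lo)) {
      s <- (v[2] - v[1]) / (mids[2] - mids[1])
      out[lo] <- v[1] + s * (frames[lo] - mids[1])
    }
    if (any(hi)) {
      s <- (v[m] - v[m - 1]) / (mids[m] - mids[m - 1])
      out[hi] <- v[m] + s * (frames[hi] - mids[m])
    }
    out
  }
  dm <- drift_model(frames, interp(sx), interp(sy), reference = reference)
  attr(dm, "peak_sharpness") <- sharp
  # peak z-scores of featureless (CSR) planes sit near the extreme-value
  # level of the noise (~7-9 sd for ~1e5 pixels); structured images score
  # an order of magnitude higher
  attr(dm, "low_confidence") <- mean(sharp, na.rm = TRUE) < 15
  dm
}

# 2D localization histogram on a fixed grid (matrix indexed [ix, iy])
.render_hist <- function(x, y, x0, y0, pixel, nx, ny) {
  ix <- pmin(pmax(floor((x - x0) / pixel), 0), nx - 1)
  iy <- pmin(pmax(floor((y - y0) / pixel), 0), ny - 1)
  m <- matrix(0, nrow = nx, ncol = ny)
  tab <- table(ix + nx * iy)
  m[as.integer(names(tab)) + 1L] <- as.integer(tab)
  m
}

# shift of image b relative to image a (in pixels) from the cross-correlation
# peak, refined per axis by parabolic interpolation through the peak and its
# two neighbours; sharpness is the peak z-score over the correlation plane
.xcorr_shift <- function(a, b, blur_px = 2) {
  nx <- 2L * nrow(a); ny <- 2L * ncol(a)
  pa <- matrix(0, nx, ny); pb <- matrix(0, nx, ny)
  pa[seq_len(nrow(a)), seq_len(ncol(a))] <- a - mean(a)
  pb[seq_len(nrow(b)), seq_len(ncol(b))] <- b - mean(b)
  fa <- stats::fft(pa); fb <- stats::fft(pb)
  # Gaussian smoothing of the correlation plane (sparse renderings give a
  # broad noisy peak; smoothing stabilises the sub-pixel refinement)
  fx <- c(0:(nx %/% 2), -rev(seq_len(nx - nx %/% 2 - 1))) / nx
  fy <- c(0:(ny %/% 2), -rev(seq_len(ny - ny %/% 2 - 1))) / ny
  g <- exp(-2 * pi^2 * blur_px^2 *
             (outer(fx^2, rep(1, ny)) + outer(rep(1, nx), fy^2)))
  cc <- Re(stats::fft(fa * Conj(fb) * g, inverse = TRUE)) / (nx * ny)
  peak <- which.max(cc)
  pi_ <- (peak - 1) %% nx; pj <- (peak - 1) %/% nx
  para <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  at <- function(i, j) cc[(i %% nx) + 1L, (j %% ny) + 1L]
  ofi <- para(at(pi_ - 1, pj), at(pi_, pj), at(pi_ + 1, pj))
  ofj <- para(at(pi_, pj - 1), at(pi_, pj), at(pi_, pj + 1))
  di <- pi_ + ofi; dj <- pj + ofj
  if (di > nx / 2) di <- di - nx
  if (dj > ny / 2) dj <- dj - ny
  sharpness <- (max(cc) - mean(cc)) / (stats::sd(cc) + 1e-12)
  # cc peak at (di, dj) means b(x) ~ a(x - d): the peak offset is minus the
  # displacement of b relative to a
  list(dx = -di, dy = -dj, sharpness = sharpness)
}

#' Read / write a drift model as CSV
#'
#' Three columns: `frame`, `dx`, `dy` (nm).
#'
#' @param path CSV path.
#' @param drift A `drift_model`.
#' @param reference Reference frame used on read (default first frame).
#' @return `read_drift` returns a `drift_model`; `write_drift` the path.
#' @export
read_drift <- function(path, reference = NULL) {
  df <- utils::read.csv(path)
  if (is.null(reference)) reference <- df$frame[1]
  drift_model(df$frame, df$dx, df$dy, reference = reference)
}

#' @rdname read_drift
#' @export
write_drift <- function(drift, path) {
  utils::write.csv(
    data.frame(frame = drift$frames, dx = drift$dx, dy = drift$dy),
    path, row.names = FALSE)
  invisible(path)
}
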