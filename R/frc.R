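#' Fourier ring correlation resolution of a localization dataset
#'
#' The table is split into two statistically independent halves (by even/odd
#' frames — the default, appropriate for blinking data — or at random), each
#' half is rendered as a 2D histogram, and the normalised correlation of the
#' two Fourier transforms is computed per spatial-frequency ring. The image
#' resolution is the inverse of the first frequency at which the smoothed
#' curve drops below 1/7.
#'
#' @param table A `loc_table` with at least 2000 localizations (override
#'   with `min_locs`).
#' @param render_pixel Rendering pixel in nm (default 10).
#' @param split `"even_odd_frames"` (default) or `"random_halves"`.
#' @param smooth_bins Moving-average window applied to the ring curve before
#'   threshold crossing (default 3).
#' @param threshold Correlation threshold (default 1/7).
#' @param min_locs Minimum table size (default 2000).
#' @return An object of class `frc_curve`: list with `frequency` (1/nm,
#'   strictly increasing), `correlation`, `resolution` (nm, or `Inf` when
#'   the curve never crosses the threshold — printed as "unresolved").
#' @export
frc_resolution <- function(table, render_pixel = 10,
                           split = c("even_odd_frames", "random_halves"),
                           smooth_bins = 3, threshold = 1 / 7,
                           min_locs = 2000) {
  split <- match.arg(split)
  if (nrow(table) < min_locs) {
    stop("need at least ", min_locs, " localizations for FRC")
  }
  if (split == "even_odd_frames") {
    selA <- table$frame %% 2 == 0
  } else {
    selA <- sample(c(TRUE, FALSE), nrow(table), replace = TRUE)
  }
  a <- table[selA, , drop = FALSE]
  b <- table[!selA, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty half after splitting")
  .frc_images(a$x, a$y, b$x, b$y, render_pixel, smooth_bins, threshold)
}

# FRC of two localization sets rendered on a common square grid
.frc_images <- function(xa, ya, xb, yb, pixel, smooth_bins, threshold) {
  x0 <- min(xa, xb); y0 <- min(ya, yb)
  nx <- ceiling((max(xa, xb) - x0) / pixel) + 1L
  ny <- ceiling((max(ya, yb) - y0) / pixel) + 1L
  n <- max(nx, ny, 16L)
  ia <- .render_hist(xa, ya, x0, y0, pixel, n, n)
  ib <- .render_hist(xb, yb, x0, y0, pixel, n, n)
  fa <- stats::fft(ia)
  fb <- stats::fft(ib)
  # ring index from centred frequency coordinates
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) # fftfreq * n
  kx <- matrix(k, n, n)
  ky <- t(kx)
  ring <- round(sqrt(kx^2 + ky^2))
  num <- Re(fa * Conj(fb))
  d1 <- Mod(fa)^2
  d2 <- Mod(fb)^2
  nr <- n %/% 2 - 1
  corr <- numeric(nr)
  for (r in seq_len(nr)) {
    sel <- ring == r
    corr[r] <- sum(num[sel]) / sqrt(sum(d1[sel]) * sum(d2[sel]) + 1e-300)
  }
  freq <- seq_len(nr) / (n * pixel)
  sm <- .moving_average(corr, smooth_bins)
  below <- which(sm < threshold)
  if (length(below) == 0) {
    res <- Inf
  } else {
    i <- below[1]
    if (i == 1) {
      res <- 1 / freq[1]
    } else {
      # linear interpolation of the crossing inside the bin
      f <- freq[i - 1] + (freq[i] - freq[i - 1]) *
        (sm[i - 1] - threshold) / (sm[i - 1] - sm[i])
      res <- 1 / f
    }
  }
  structure(list(frequency = freq, correlation = corr,
                 smoothed = sm, resolution = res,
                 threshold = threshold, pixel = pixel),
            class = "frc_curve")
}

#' @export
print.frc_curve <- function(x, ...) {
  if (is.finite(x$resolution)) {
    cat(sprintf("<frc_curve> resolution %.1f nm (1/%.0f threshold, %g nm px)\n",
                x$resolution, 1 / x$threshold, x$pixel))
  } else {
    cat("<frc_curve> unresolved (curve never crosses the threshold)\n")
  }
  invisible(x)
}
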