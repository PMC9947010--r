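#' Detect intensity foci in a 2D image (find-maxima with noise tolerance)
#'
#' Prominence-based spot detection on a maximum-projection image: pixels are
#' flooded in decreasing intensity order; a local maximum survives as a
#' focus only if it stands more than `noise_tolerance` above the saddle at
#' which its catchment basin meets a higher one. Plateaus yield a single
#' focus at their lowest linear pixel index. Adding a constant to the image
#' does not change the result.
#'
#' @param image Numeric matrix (2D grayscale).
#' @param noise_tolerance Minimum prominence above the merging saddle.
#' @return Integer matrix with columns `row`, `col` (one row per focus),
#'   ordered by decreasing peak intensity.
#' @export
detect_foci <- function(image, noise_tolerance) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a 2D numeric matrix")
  }
  if (noise_tolerance <= 0) stop("noise_tolerance must be > 0")
  nr <- nrow(image); nc <- ncol(image)
  npix <- nr * nc
  ord <- order(-as.numeric(image), seq_len(npix))
  region <- integer(npix)              # 0 = unassigned
  peak_val <- numeric(0)               # per region
  peak_pix <- integer(0)
  is_max <- logical(0)
  last_val <- numeric(0)               # lowest level reached by the region
  parent <- integer(0)
  findr <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (p in ord) {
    v <- image[p]
    r0 <- (p - 1) %% nr + 1L
    c0 <- (p - 1) %/% nr + 1L
    nbr <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r0 + dr; cc <- c0 + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      q <- rr + (cc - 1L) * nr
      if (region[q] > 0) nbr <- c(nbr, findr(region[q]))
    }
    nbr <- unique(nbr)
    if (length(nbr) == 0) {
      k <- length(parent) + 1L
      parent[k] <- k
      peak_val[k] <- v
      peak_pix[k] <- p
      is_max[k] <- TRUE
      last_val[k] <- v
      region[p] <- k
    } else {
      # join the region with the highest peak; merge others into it
      main <- nbr[which.max(peak_val[nbr])]
      region[p] <- main
      last_val[main] <- v
      for (r in setdiff(nbr, main)) {
        if (peak_val[r] - v < noise_tolerance) {
          is_max[r] <- FALSE       # absorbed: never was a separate max
        }
        parent[r] <- main
        last_val[main] <- min(last_val[main], last_val[r])
      }
    }
  }
  cand <- which(is_max)
  # surviving candidates need prominence over the flooded area they ended in
  conf <- cand[vapply(cand, function(k) {
    root <- findr(k)
    peak_val[k] - last_val[root] >= noise_tolerance
  }, logical(1))]
  if (length(conf) == 0) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("row", "col"))))
  }
  conf <- conf[order(-peak_val[conf], peak_pix[conf])]
  px <- peak_pix[conf]
  cbind(row = (px - 1L) %% nr + 1L, col = (px - 1L) %/% nr + 1L)
}

#' Foci density inside a cell mask
#'
#' @param foci Two-column matrix from [detect_foci()] (row, col).
#' @param mask Logical matrix marking the cell region.
#' @param pixel_size Pixel edge in micrometres.
#' @return List with `count` (foci inside the mask), `area_um2` and
#'   `density` (foci per um^2).
#' @export
foci_density <- function(foci, mask, pixel_size) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("mask must be a logical matrix")
  }
  npx <- sum(mask)
  if (npx == 0) stop("empty cell mask")
  inside <- if (nrow(foci)) mask[cbind(foci[, 1], foci[, 2])] else logical(0)
  area <- npx * pixel_size^2
  list(count = sum(inside), area_um2 = area, density = sum(inside) / area)
}

#' Phagocytic index from flow-cytometry engulfment percentages
#'
#' The percentage of target cells engulfed under a condition, background-
#' subtracted with its cytochalasin-D control (engulfment-incompetent
#' macrophages) and normalised to the equally background-subtracted
#' untreated condition:
#' `(p_cond - p_cond_cytd) / (p_ctrl - p_ctrl_cytd)`.
#' Negative numerators are clamped to 0 with a warning.
#'
#' @param p_cond,p_cond_cytd Percent engulfed for the condition and its
#'   CytD control.
#' @param p_ctrl,p_ctrl_cytd Same for the untreated reference.
#' @return The dimensionless index.
#' @export
phagocytic_index <- function(p_cond, p_cond_cytd, p_ctrl, p_ctrl_cytd) {
  pct <- c(p_cond, p_cond_cytd, p_ctrl, p_ctrl_cytd)
  if (any(pct < 0 | pct > 100)) stop("percentages must be in [0, 100]")
  den <- p_ctrl - p_ctrl_cytd
  if (den <= 0) stop("control minus its CytD background must be positive")
  num <- p_cond - p_cond_cytd
  if (num < 0) {
    warning("condition below its CytD background; index clamped to 0")
    num <- 0
  }
  num / den
}
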