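#' Coordinate-based Spearman co-localization of two channels
#'
#' For every localization position p of either channel (optionally inside a
#' rectangular ROI), the pair `(deltaA(p), deltaB(p))` of first-rank Voronoi
#' densities is formed, where `deltaX(p)` is the density of the channel-X
#' cell containing p (the cell of the nearest channel-X localization).
#' The reported statistic is the Spearman rank correlation over all pairs
#' (ties mid-ranked); the per-channel variants restricted to channel-A or
#' channel-B positions are reported alongside.
#'
#' @param tableA,tableB `loc_table`s (or n x 2 matrices) of the two
#'   channels.
#' @param roi Optional rectangle `c(xmin, xmax, ymin, ymax)` in nm.
#' @return An object of class `coloc_result` with `rho` (pooled), `rho_A`,
#'   `rho_B` and `n` (pairs used).
#' @export
spearman_coloc <- function(tableA, tableB, roi = NULL) {
  pa <- .coords(tableA); pb <- .coords(tableB)
  if (!is.null(roi)) {
    pa <- .clip_roi(pa, roi); pb <- .clip_roi(pb, roi)
  }
  if (nrow(pa) < 4 || nrow(pb) < 4) {
    stop("need at least 4 localizations per channel (inside the ROI)")
  }
  dmA <- voronoi_densities(pa)
  dmB <- voronoi_densities(pb)
  allp <- rbind(pa, pb)
  from_a <- c(rep(TRUE, nrow(pa)), rep(FALSE, nrow(pb)))
  ia <- .nn_index(allp, pa)
  ib <- .nn_index(allp, pb)
  da <- dmA$delta_i[ia]
  db <- dmB$delta_i[ib]
  # pairs touching the tessellation border in either channel are dropped:
  # both channels share a low-density rim there, which would correlate
  # even spatially unrelated patterns
  ok <- !is.na(da) & !is.na(db) &
    !dmA$boundary2[ia] & !dmB$boundary2[ib]
  if (sum(ok) < 3) stop("too few interior pairs for a correlation")
  if (stats::sd(da[ok]) == 0 || stats::sd(db[ok]) == 0) {
    stop("degenerate (constant) density in one channel")
  }
  sp <- function(u, v) stats::cor(u, v, method = "spearman")
  rho <- sp(da[ok], db[ok])
  okA <- ok & from_a; okB <- ok & !from_a
  structure(list(
    rho = rho,
    rho_A = if (sum(okA) >= 3) sp(da[okA], db[okA]) else NA_real_,
    rho_B = if (sum(okB) >= 3) sp(da[okB], db[okB]) else NA_real_,
    n = sum(ok)), class = "coloc_result")
}

.coords <- function(x) {
  if (is.matrix(x)) x else cbind(x$x, x$y)
}

.clip_roi <- function(p, roi) {
  stopifnot(length(roi) == 4)
  p[p[, 1] >= roi[1] & p[, 1] <= roi[2] &
    p[, 2] >= roi[3] & p[, 2] <= roi[4], , drop = FALSE]
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> Spearman rho = %.3f (A: %.3f, B: %.3f), n = %d\n",
              x$rho, x$rho_A, x$rho_B, x$n))
  if (!is.null(x$M_A)) {
    cat(sprintf("  Manders M_A = %.3f, M_B = %.3f\n", x$M_A, x$M_B))
  }
  invisible(x)
}

#' Manders coefficients from Voronoi-thresholded dense regions
#'
#' Each channel is segmented at `density_factor` times its mean first-rank
#' density; `M_A` is the fraction of channel-A localizations lying inside
#' the dense region of channel B (point-in-dense-Voronoi-cell test via the
#' nearest channel-B cell), and `M_B` symmetrically.
#'
#' @param tableA,tableB `loc_table`s (or n x 2 matrices).
#' @param density_factor Dense threshold as multiple of the mean density.
#' @return List with `M_A`, `M_B` in `[0, 1]`.
#' @export
manders_coloc <- function(tableA, tableB, density_factor = 1) {
  pa <- .coords(tableA); pb <- .coords(tableB)
  if (nrow(pa) == 0 || nrow(pb) == 0) stop("empty channel")
  dmA <- voronoi_densities(pa)
  dmB <- voronoi_densities(pb)
  denseA <- !dmA$hull & !is.na(dmA$delta_i) &
    dmA$delta_i >= density_factor * dmA$delta
  denseB <- !dmB$hull & !is.na(dmB$delta_i) &
    dmB$delta_i >= density_factor * dmB$delta
  M_A <- mean(denseB[.nn_index(pa, pb)])
  M_B <- mean(denseA[.nn_index(pb, pa)])
  list(M_A = M_A, M_B = M_B)
}

#' Artificial positive control: even/odd frame split
#'
#' Splitting one acquisition by frame parity yields two channels imaging the
#' same underlying structure — the reference for maximal expected
#' co-localization.
#'
#' @param table A `loc_table` spanning at least 2 distinct frames.
#' @return List of `loc_table`s `A` (even frames) and `B` (odd frames).
#' @export
control_positive <- function(table) {
  if (length(unique(table$frame)) < 2) {
    stop("need at least 2 distinct frames to split")
  }
  even <- table$frame %% 2 == 0
  list(A = table[even, , drop = FALSE], B = table[!even, , drop = FALSE])
}

#' Artificial negative control: vertical flip
#'
#' Reflects all localizations about the horizontal midline of the bounding
#' box (`y -> ymin + ymax - y`); applying the control twice restores the
#' original table.
#'
#' @param table A `loc_table`.
#' @param bounding_box `c(xmin, xmax, ymin, ymax)`; defaults to the data
#'   bounding box. All points must lie inside it.
#' @return The flipped `loc_table`.
#' @export
control_negative <- function(table, bounding_box = NULL) {
  if (is.null(bounding_box)) {
    bounding_box <- c(range(table$x), range(table$y))
  }
  if (any(table$x < bounding_box[1] | table$x > bounding_box[2] |
          table$y < bounding_box[3] | table$y > bounding_box[4])) {
    stop("localizations outside the bounding box")
  }
  table$y <- bounding_box[3] + bounding_box[4] - table$y
  table
}
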