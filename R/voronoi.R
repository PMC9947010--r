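#' Voronoi density map of a localization pattern
#'
#' Computes the Voronoi tessellation of the localization positions and, per
#' localization, the first-rank local density
#' `delta_i = (N_i + 1) / (area of cell i + areas of its N_i edge-adjacent
#' cells)` — the cell-plus-neighbours convention that smooths single-cell
#' noise. Points on the convex hull own unbounded cells: they are flagged,
#' given `NA` density, excluded from the dataset mean density `delta` and
#' never counted as neighbours. Cocircular point configurations produce
#' zero-length Voronoi edges; such degenerate contacts are not treated as
#' adjacency.
#'
#' @param table A `loc_table`, or an n x 2 matrix of positions (nm).
#' @param density One of `"first_rank"` (default) or `"cell"` (plain
#'   1/area).
#' @return An object of class `density_map`: list with `x`, `y`, `area`
#'   (nm^2, NA on the hull), `hull` (logical), `delta_i` (per-point density,
#'   localizations/nm^2), `delta` (mean over interior points), `edges`
#'   (two-column adjacency matrix, 1-based point indices) and `n`.
#' @export
voronoi_densities <- function(table, density = c("first_rank", "cell")) {
  density <- match.arg(density)
  pts <- if (is.matrix(table)) table else cbind(table$x, table$y)
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 points to tessellate")
  if (stats::sd(pts[, 1]) == 0 || stats::sd(pts[, 2]) == 0) {
    stop("points are collinear; tessellation undefined")
  }
  # exact duplicates break the triangulation: nudge deterministically
  dup <- duplicated(pts)
  if (any(dup)) {
    scale <- max(diff(range(pts[, 1])), diff(range(pts[, 2])))
    k <- which(dup)
    pts[k, 1] <- pts[k, 1] + (seq_along(k)) * 1e-9 * scale
    pts[k, 2] <- pts[k, 2] + (seq_along(k)) * 0.7e-9 * scale
  }
  vt <- .delaunay_voronoi(pts)
  area <- vt$area
  hull <- vt$hull
  diag_len <- sqrt(diff(range(pts[, 1]))^2 + diff(range(pts[, 2]))^2)
  keep <- vt$edge_vlen > 1e-9 * diag_len  # drop degenerate and hull duals
  ei <- vt$edge_i[keep]; ej <- vt$edge_j[keep]
  if (density == "first_rank") {
    # neighbour sums restricted to interior (finite-area) cells
    ok <- !hull[ei] & !hull[ej]
    fi <- c(ei[ok], ej[ok]); fj <- c(ej[ok], ei[ok])
    nb_area <- rep(0, n); nb_cnt <- rep(0L, n)
    if (length(fi)) {
      s <- rowsum(area[fj], fi)
      cts <- rowsum(rep(1L, length(fi)), fi)
      idx <- as.integer(rownames(s))
      nb_area[idx] <- s[, 1]
      nb_cnt[idx] <- cts[, 1]
    }
    delta_i <- ifelse(hull, NA_real_, (nb_cnt + 1) / (area + nb_area))
  } else {
    delta_i <- ifelse(hull, NA_real_, 1 / area)
  }
  # rank-2 boundary: interior points adjacent to a hull point; their own
  # density is biased low by the unbounded neighbourhood and co-localization
  # pairing excludes them (a shared low-density rim would otherwise
  # correlate even independent channels)
  boundary2 <- hull
  touch <- c(ei[hull[ej]], ej[hull[ei]])
  boundary2[touch] <- TRUE
  structure(list(x = pts[, 1], y = pts[, 2], area = area, hull = hull,
                 boundary2 = boundary2,
                 delta_i = delta_i,
                 delta = mean(delta_i[!hull]),
                 edges = cbind(i = ei, j = ej), n = n,
                 density = density),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "<density_map> %d points (%d on hull), mean density %.4g /nm^2 (%s)\n",
    x$n, sum(x$hull), x$delta, x$density))
  invisible(x)
}

#' Segment clusters from a Voronoi density map
#'
#' Localizations whose first-rank density reaches `density_factor` times the
#' dataset mean density are "dense"; clusters are the connected components
#' of dense points under Voronoi adjacency, discarding components smaller
#' than `min_locs`. Cluster area is the sum of member cell areas and the
#' diameter is the equivalent-circle value `2*sqrt(area/pi)`.
#'
#' @param table A `loc_table` or n x 2 matrix, or a precomputed
#'   `density_map`.
#' @param density_factor Threshold as a multiple of the mean density
#'   (default 1).
#' @param min_locs Minimum localizations per retained cluster (default 25).
#' @return An object of class `cluster_set`: data.frame `clusters`
#'   (`cluster`, `n_locs`, `area`, `diameter`), `members` (list of point
#'   indices), `dense` (logical per point), `map` (the density map).
#' @export
segment_clusters <- function(table, density_factor = 1, min_locs = 25) {
  dm <- if (inherits(table, "density_map")) table else
    voronoi_densities(table)
  dense <- !dm$hull & !is.na(dm$delta_i) &
    dm$delta_i >= density_factor * dm$delta
  ei <- dm$edges[, 1]; ej <- dm$edges[, 2]
  sel <- dense[ei] & dense[ej]
  comp <- .union_find(dm$n, ei[sel], ej[sel])
  comp[!dense] <- NA_integer_
  memb <- split(which(dense), comp[dense])
  memb <- memb[lengths(memb) >= min_locs]
  if (length(memb)) {
    area <- vapply(memb, function(ix) sum(dm$area[ix]), numeric(1))
    cl <- data.frame(cluster = seq_along(memb),
                     n_locs = lengths(memb),
                     area = unname(area),
                     diameter = 2 * sqrt(unname(area) / pi))
    o <- order(-cl$n_locs)
    cl <- cl[o, , drop = FALSE]
    cl$cluster <- seq_len(nrow(cl))
    rownames(cl) <- NULL
    memb <- memb[o]
    names(memb) <- NULL
  } else {
    cl <- data.frame(cluster = integer(0), n_locs = integer(0),
                     area = numeric(0), diameter = numeric(0))
    memb <- list()
  }
  structure(list(clusters = cl, members = memb, dense = dense, map = dm),
            class = "cluster_set")
}

# connected components by union-find with path halving
.union_find <- function(n, ei, ej) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(ei)) {
    a <- find(ei[k]); b <- find(ej[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1))
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s), %d dense / %d points\n",
              nrow(x$clusters), sum(x$dense), x$map$n))
  if (nrow(x$clusters)) print(utils::head(x$clusters, 8), ...)
  invisible(x)
}

#' Equivalent-circle diameters of segmented clusters
#'
#' @param clusters A `cluster_set`.
#' @return Numeric vector of diameters in nm.
#' @export
cluster_diameters <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  clusters$clusters$diameter
}

#' Write a cluster table as CSV
#'
#' Columns: cluster id, n_locs, area (nm^2), diameter (nm).
#'
#' @param clusters A `cluster_set`.
#' @param path Output path.
#' @export
write_clusters <- function(clusters, path) {
  utils::write.csv(clusters$clusters, path, row.names = FALSE)
  invisible(path)
}
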