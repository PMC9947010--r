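#' Link localizations into tracks by greedy nearest-neighbour assignment
#'
#' Deterministic frame-by-frame linker: localizations of frame f are matched
#' to open track ends in ascending order of pairwise distance, each end and
#' each localization used at most once; candidate pairs farther apart than
#' `max_link_distance` are rejected, unmatched localizations start new
#' tracks and ends unmatched for more than `max_frame_gap` frames are
#' closed. Equidistant candidates are resolved by the lower localization id
#' (then lower track id), so linking is reproducible.
#'
#' @param table A drift-corrected, single-channel `loc_table`.
#' @param max_link_distance Maximum jump in nm accepted between frames.
#' @param max_frame_gap Frames an end may stay dark and still be linked
#'   (default 0: consecutive frames only).
#' @return A `trackset` data.frame with columns `track_id`, `frame`, `x`,
#'   `y`, `loc_id`.
#' @export
link_tracks <- function(table, max_link_distance, max_frame_gap = 0) {
  if (max_link_distance < 0 || max_frame_gap < 0) {
    stop("linking parameters must be non-negative")
  }
  if (length(unique(table$channel)) > 1) stop("linking needs a single channel")
  ord <- order(table$frame, table$id)
  fr <- table$frame[ord]; xx <- table$x[ord]; yy <- table$y[ord]
  ids <- table$id[ord]
  n <- length(fr)
  track_of <- integer(n)
  # open ends: parallel vectors
  e_track <- integer(0); e_x <- numeric(0); e_y <- numeric(0)
  e_frame <- integer(0)
  next_track <- 1L
  for (f in unique(fr)) {
    pts <- which(fr == f)
    live <- which(e_frame >= f - 1L - max_frame_gap)
    if (length(live) && length(pts)) {
      d <- sqrt(outer(xx[pts], e_x[live], "-")^2 +
                outer(yy[pts], e_y[live], "-")^2)
      cand <- which(d <= max_link_distance, arr.ind = TRUE)
      if (nrow(cand)) {
        o <- order(d[cand], ids[pts[cand[, 1]]], e_track[live[cand[, 2]]])
        cand <- cand[o, , drop = FALSE]
        used_p <- logical(length(pts)); used_e <- logical(length(live))
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (used_p[i] || used_e[j]) next
          used_p[i] <- TRUE; used_e[j] <- TRUE
          g <- live[j]
          track_of[pts[i]] <- e_track[g]
          e_x[g] <- xx[pts[i]]; e_y[g] <- yy[pts[i]]; e_frame[g] <- f
        }
        pts <- pts[!used_p]
      }
    }
    # drop ends that can no longer be extended
    stale <- e_frame < f - max_frame_gap
    if (any(stale)) {
      keep <- !stale
      e_track <- e_track[keep]; e_x <- e_x[keep]; e_y <- e_y[keep]
      e_frame <- e_frame[keep]
    }
    if (length(pts)) {
      nt <- length(pts)
      new_ids <- next_track:(next_track + nt - 1L)
      next_track <- next_track + nt
      track_of[pts] <- new_ids
      e_track <- c(e_track, new_ids)
      e_x <- c(e_x, xx[pts]); e_y <- c(e_y, yy[pts])
      e_frame <- c(e_frame, rep(f, nt))
    }
  }
  out <- data.frame(track_id = track_of, frame = fr, x = xx, y = yy,
                    loc_id = ids)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trackset", "data.frame")
  out
}

#' Keep only tracks with more than a minimum number of localizations
#'
#' Short tracks carry too few jumps for a stable per-track mean jump
#' distance; the default keeps tracks with strictly more than 10
#' localizations (i.e. at least 11).
#'
#' @param trackset A `trackset`.
#' @param min_localizations Minimum track size kept (default 11).
#' @return The filtered `trackset` with attributes `n_kept`/`n_removed`
#'   (track counts).
#' @export
filter_tracks <- function(trackset, min_localizations = 11) {
  sizes <- table(trackset$track_id)
  keep_ids <- as.integer(names(sizes)[sizes >= min_localizations])
  out <- trackset[trackset$track_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trackset", "data.frame")
  attr(out, "n_kept") <- length(keep_ids)
  attr(out, "n_removed") <- length(sizes) - length(keep_ids)
  out
}

#' Mean jump distance of one track
#'
#' Average Euclidean distance travelled between *consecutive* frames;
#' position pairs spanning a frame gap are excluded.
#'
#' @param track A data.frame with `frame`, `x`, `y` (one track).
#' @return The MJD in nm.
#' @export
compute_mjd <- function(track) {
  track <- track[order(track$frame), , drop = FALSE]
  dfr <- diff(track$frame)
  sel <- dfr == 1
  if (!any(sel)) stop("track has no consecutive-frame pair; MJD undefined")
  jumps <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  mean(jumps[sel])
}

#' Per-track mean jump distances of a track set
#'
#' Vectorised [compute_mjd()] over all tracks; tracks without any
#' consecutive-frame pair get `NA`.
#'
#' @param trackset A `trackset`.
#' @return Named numeric vector of MJDs (names = track ids).
#' @export
track_mjds <- function(trackset) {
  ord <- order(trackset$track_id, trackset$frame)
  tid <- trackset$track_id[ord]
  fr <- trackset$frame[ord]
  x <- trackset$x[ord]; y <- trackset$y[ord]
  same <- diff(tid) == 0 & diff(fr) == 1
  jump <- sqrt(diff(x)^2 + diff(y)^2)
  jt <- tid[-length(tid)][same]
  sums <- rowsum(jump[same], jt)
  cnts <- rowsum(rep(1, length(jt)), jt)
  mjd <- as.numeric(sums / cnts)
  names(mjd) <- rownames(sums)
  all_ids <- as.character(unique(tid))
  out <- stats::setNames(rep(NA_real_, length(all_ids)), all_ids)
  out[names(mjd)] <- mjd
  out
}

#' Histogram of mean jump distances
#'
#' Left-closed bins of fixed width over a fixed range; values beyond the
#' range are counted in an overflow bin so the total is conserved.
#'
#' @param mjds Numeric MJDs (NA dropped), or a `trackset`.
#' @param bin_width Bin width in nm (default 10).
#' @param range Histogram range in nm (default `c(0, 400)`).
#' @return A list with `breaks`, `mids`, `counts`, `overflow`, `n`.
#' @export
mjd_histogram <- function(mjds, bin_width = 10, range = c(0, 400)) {
  if (bin_width <= 0) stop("bin width must be positive")
  if (inherits(mjds, "trackset")) mjds <- track_mjds(mjds)
  mjds <- mjds[!is.na(mjds)]
  if (length(mjds) == 0) stop("no MJDs to histogram")
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  inside <- mjds >= range[1] & mjds < breaks[length(breaks)]
  idx <- findInterval(mjds[inside], breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  list(breaks = breaks,
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       counts = counts,
       overflow = sum(!inside),
       n = length(mjds))
}

#' Classify tracks into low- and high-mobility classes
#'
#' MJDs below the threshold (default 140 nm) are "low", at or above it
#' "high" (the boundary value is assigned to the high class).
#'
#' @param mjds Numeric MJDs or a `trackset`.
#' @param threshold Class boundary in nm (default 140).
#' @return Factor of labels with attribute `prop_high`.
#' @export
classify_tracks <- function(mjds, threshold = 140) {
  if (inherits(mjds, "trackset")) mjds <- track_mjds(mjds)
  lab <- factor(ifelse(mjds >= threshold, "high", "low"),
                levels = c("low", "high"))
  attr(lab, "prop_high") <- if (length(lab)) mean(lab == "high",
                                                  na.rm = TRUE) else NA_real_
  lab
}
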