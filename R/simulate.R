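#' @useDynLib smlmtools, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# evaluate expr under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration for Brownian track simulation
#'
#' Defaults reflect a TIRF single-particle-tracking acquisition at 33 Hz on
#' a 256-pixel EMCCD region at 160 nm/pixel (field 40.96 um) with ~25 nm
#' per-axis localization precision.
#'
#' @param n_tracks Number of tracks.
#' @param track_length Frames per track.
#' @param frame_interval Seconds between frames (default 1/33).
#' @param populations List of `c(D = um^2/s, weight = fraction)` pairs;
#'   weights must sum to 1.
#' @param loc_precision Per-axis localization SD in nm.
#' @param field_size Field width/height in nm (length-2 or scalar).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `sim_track_config` list.
#' @export
sim_track_config <- function(n_tracks = 1000, track_length = 50,
                             frame_interval = 1 / 33,
                             populations = list(c(D = 0.111, weight = 2 / 3),
                                                c(D = 0.293, weight = 1 / 3)),
                             loc_precision = 24.8,
                             field_size = c(40960, 40960),
                             seed = NULL) {
  field_size <- rep_len(field_size, 2)
  w <- vapply(populations, function(p) p[["weight"]], numeric(1))
  D <- vapply(populations, function(p) p[["D"]], numeric(1))
  if (abs(sum(w) - 1) > 1e-9) stop("population weights must sum to 1")
  if (any(D < 0)) stop("diffusion coefficients must be >= 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (n_tracks <= 0) stop("n_tracks must be positive")
  if (any(field_size <= 0)) stop("field size must be positive")
  structure(list(n_tracks = as.integer(n_tracks),
                 track_length = as.integer(track_length),
                 frame_interval = frame_interval,
                 D = D, weights = w,
                 loc_precision = loc_precision,
                 field_size = field_size, seed = seed),
            class = "sim_track_config")
}

#' Simulate two-dimensional Brownian tracks with localization noise
#'
#' Each track belongs to one diffusion population (per-axis step SD
#' `sqrt(2 D dt)`), starts uniformly in the field, reflects at the field
#' edges, and is observed with independent per-axis Gaussian localization
#' noise. For a population the expected jump distance between consecutive
#' observed frames is the closed form `sqrt(pi * (D * dt + sigma_loc^2))`.
#'
#' @param config A [sim_track_config()].
#' @return A list with `tracks` (class `trackset`: data.frame `track_id`,
#'   `frame`, `x`, `y`), `population` (integer label per track),
#'   and `table` (the corresponding `loc_table`).
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_track_config"))
  .with_seed(config$seed, {
    nt <- config$n_tracks
    len <- config$track_length
    pop <- sample.int(length(config$weights), nt, replace = TRUE,
                      prob = config$weights)
    step_sd <- sqrt(2 * config$D * 1e6 * config$frame_interval)  # nm/axis
    fx <- config$field_size[1]; fy <- config$field_size[2]
    # true positions: cumulated reflected random walks, vectorised over tracks
    x <- matrix(0, nrow = len, ncol = nt)
    y <- matrix(0, nrow = len, ncol = nt)
    x[1, ] <- stats::runif(nt, 0, fx)
    y[1, ] <- stats::runif(nt, 0, fy)
    sds <- step_sd[pop]
    for (f in seq_len(len - 1)) {
      x[f + 1, ] <- .reflect(x[f, ] + stats::rnorm(nt, 0, sds), fx)
      y[f + 1, ] <- .reflect(y[f, ] + stats::rnorm(nt, 0, sds), fy)
    }
    obsx <- x + stats::rnorm(len * nt, 0, config$loc_precision)
    obsy <- y + stats::rnorm(len * nt, 0, config$loc_precision)
    tracks <- data.frame(
      track_id = rep(seq_len(nt), each = len),
      frame = rep.int(0:(len - 1), nt),
      x = as.numeric(obsx), y = as.numeric(obsy))
    class(tracks) <- c("trackset", "data.frame")
    attr(tracks, "population") <- pop
    tab <- loc_table(frame = tracks$frame, x = tracks$x, y = tracks$y,
                     track_id = tracks$track_id)
    list(tracks = tracks, population = pop, table = tab)
  })
}

.reflect <- function(v, upper) {
  # reflective boundary on [0, upper]; handles multiple bounces
  v <- v %% (2 * upper)
  ifelse(v > upper, 2 * upper - v, v)
}

#' Configuration for clustered blinking-emitter simulation
#'
#' Emulates a STORM acquisition of a clustered membrane protein: emitters
#' grouped in uniform disks over a CSR background, each emitter blinking
#' `1 + Poisson(blinks_per_emitter)` times on random frames, every
#' localization jittered by the localization precision.
#'
#' @param n_clusters Number of disk clusters.
#' @param cluster_radius Disk radius in nm.
#' @param locs_per_cluster Emitters per cluster (each contributes
#'   `1 + Poisson(blinks_per_emitter)` localizations).
#' @param background_density Background emitters per um^2 (CSR).
#' @param blinks_per_emitter Mean extra localizations per emitter.
#' @param loc_precision Per-axis jitter SD in nm.
#' @param field_size Field in nm (length-2 or scalar).
#' @param n_frames Frames in the acquisition.
#' @param seed Integer seed.
#' @return A `sim_cluster_config` list.
#' @export
sim_cluster_config <- function(n_clusters = 20, cluster_radius = 150,
                               locs_per_cluster = 200,
                               background_density = 10,
                               blinks_per_emitter = 0,
                               loc_precision = 10,
                               field_size = c(10000, 10000),
                               n_frames = 10000, seed = NULL) {
  field_size <- rep_len(field_size, 2)
  if (n_clusters < 0 || locs_per_cluster < 0 || background_density < 0 ||
      blinks_per_emitter < 0 || n_frames <= 0) {
    stop("counts must be non-negative and n_frames positive")
  }
  if (cluster_radius <= 0) stop("cluster_radius must be > 0")
  if (n_clusters > 0 && 2 * cluster_radius > min(field_size)) {
    stop("cluster diameter exceeds the field size")
  }
  structure(list(n_clusters = as.integer(n_clusters),
                 cluster_radius = cluster_radius,
                 locs_per_cluster = as.integer(locs_per_cluster),
                 background_density = background_density,
                 blinks_per_emitter = blinks_per_emitter,
                 loc_precision = loc_precision,
                 field_size = field_size,
                 n_frames = as.integer(n_frames), seed = seed),
            class = "sim_cluster_config")
}

#' Simulate a clustered blinking-emitter localization table
#'
#' @param config A [sim_cluster_config()].
#' @return A list with `table` (a `loc_table` with `emitter` column) and
#'   `truth` (data.frame of emitters: id, true x/y, cluster id with 0 for
#'   background) plus `centers` (cluster centres) and the config.
#' @export
simulate_clustered_points <- function(config) {
  stopifnot(inherits(config, "sim_cluster_config"))
  .with_seed(config$seed, {
    fx <- config$field_size[1]; fy <- config$field_size[2]
    r <- config$cluster_radius
    # cluster centres uniform, kept fully inside the field
    cx <- stats::runif(config$n_clusters, r, fx - r)
    cy <- stats::runif(config$n_clusters, r, fy - r)
    ne_c <- config$n_clusters * config$locs_per_cluster
    if (ne_c > 0) {
      rad <- r * sqrt(stats::runif(ne_c))
      th <- stats::runif(ne_c, 0, 2 * pi)
      ex <- rep(cx, each = config$locs_per_cluster) + rad * cos(th)
      ey <- rep(cy, each = config$locs_per_cluster) + rad * sin(th)
      ecl <- rep(seq_len(config$n_clusters), each = config$locs_per_cluster)
    } else {
      ex <- ey <- numeric(0); ecl <- integer(0)
    }
    area_um2 <- fx * fy / 1e6
    n_bg <- stats::rpois(1, config$background_density * area_um2)
    ex <- c(ex, stats::runif(n_bg, 0, fx))
    ey <- c(ey, stats::runif(n_bg, 0, fy))
    ecl <- c(ecl, rep(0L, n_bg))
    ne <- length(ex)
    truth <- data.frame(emitter = seq_len(ne), x = ex, y = ey, cluster = ecl)
    nloc <- 1L + stats::rpois(ne, config$blinks_per_emitter)
    emitter <- rep.int(seq_len(ne), nloc)
    m <- length(emitter)
    tab <- loc_table(
      frame = sample.int(config$n_frames, m, replace = TRUE) - 1L,
      x = ex[emitter] + stats::rnorm(m, 0, config$loc_precision),
      y = ey[emitter] + stats::rnorm(m, 0, config$loc_precision),
      emitter = emitter)
    list(table = tab, truth = truth,
         centers = data.frame(x = cx, y = cy), config = config)
  })
}

#' Derive a second acquisition channel from a simulated table
#'
#' Three generative relationships between the channels are supported:
#' `"coclustered"` re-samples fresh blinking localizations from the same
#' ground-truth emitters (same nanoscale structure, independent noise),
#' `"independent"` draws a spatially unrelated CSR channel with the same
#' number of localizations over the same field, and `"mirrored"` vertically
#' flips the channel-A localizations (the classical negative control).
#' Channel B is finally mapped through the chromatic `transform`.
#'
#' @param table Channel-A `loc_table`.
#' @param truth Emitter ground truth from [simulate_clustered_points()]
#'   (required for `"coclustered"`).
#' @param transform An `affine2d` (default identity).
#' @param mode One of `"coclustered"`, `"independent"`, `"mirrored"`.
#' @param field_size Field in nm used for `"independent"` and `"mirrored"`.
#' @param loc_precision Jitter for re-sampled localizations (nm).
#' @param blinks_per_emitter Mean extra blinks for `"coclustered"`.
#' @param seed Integer seed.
#' @return A list with `A` and `B` localization tables (channels 1 and 2).
#' @export
make_two_channel <- function(table, truth = NULL,
                             transform = affine_transform(),
                             mode = c("coclustered", "independent",
                                      "mirrored"),
                             field_size = c(10000, 10000),
                             loc_precision = 10, blinks_per_emitter = 0,
                             seed = NULL) {
  mode <- match.arg(mode)
  field_size <- rep_len(field_size, 2)
  .with_seed(seed, {
    if (mode == "coclustered") {
      if (is.null(truth)) stop("coclustered mode needs the emitter truth")
      ne <- nrow(truth)
      nloc <- 1L + stats::rpois(ne, blinks_per_emitter)
      emitter <- rep.int(seq_len(ne), nloc)
      m <- length(emitter)
      nfr <- max(table$frame) + 1L
      B <- loc_table(frame = sample.int(nfr, m, replace = TRUE) - 1L,
                     x = truth$x[emitter] + stats::rnorm(m, 0, loc_precision),
                     y = truth$y[emitter] + stats::rnorm(m, 0, loc_precision),
                     channel = 2L, emitter = emitter)
    } else if (mode == "independent") {
      m <- nrow(table)
      B <- loc_table(frame = sample.int(max(table$frame) + 1L, m,
                                        replace = TRUE) - 1L,
                     x = stats::runif(m, 0, field_size[1]),
                     y = stats::runif(m, 0, field_size[2]),
                     channel = 2L)
    } else {
      B <- table
      B$y <- field_size[2] - B$y
      B$channel <- 2L
      B <- as_loc_table(as.data.frame(B))
    }
    B <- apply_transform(B, transform)
    list(A = table, B = B)
  })
}

#' Add static fiducial markers to a localization table
#'
#' `n` bright immobile emitters, localized in every frame of the acquisition
#' with the stated precision, are appended and labelled through a
#' `fiducial` column (NA for ordinary localizations).
#'
#' @param table A `loc_table`.
#' @param n Number of fiducials (0 returns the table unchanged).
#' @param brightness Photon count stored in `intensity`.
#' @param loc_precision Per-axis jitter SD in nm (fiducials are localized
#'   very precisely; default 2 nm).
#' @param n_frames Frames to cover (default `max(frame) + 1`).
#' @param field_size Field in nm for placing the markers.
#' @param seed Integer seed.
#' @return A list with `table` (augmented `loc_table`) and `fiducial_ids`
#'   (list of localization-id vectors, one per fiducial).
#' @export
add_fiducials <- function(table, n, brightness = 5e4, loc_precision = 2,
                          n_frames = NULL, field_size = NULL, seed = NULL) {
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(list(table = table, fiducial_ids = list()))
  if (is.null(n_frames)) n_frames <- max(table$frame) + 1L
  if (is.null(field_size)) {
    field_size <- c(max(table$x), max(table$y))
  }
  field_size <- rep_len(field_size, 2)
  .with_seed(seed, {
    px <- stats::runif(n, 0.1, 0.9) * field_size[1]
    py <- stats::runif(n, 0.1, 0.9) * field_size[2]
    m <- n * n_frames
    fid <- rep(seq_len(n), each = n_frames)
    id0 <- if (nrow(table)) max(table$id) else 0L
    add <- data.frame(
      id = id0 + seq_len(m),
      frame = rep.int(0:(n_frames - 1L), n),
      x = px[fid] + stats::rnorm(m, 0, loc_precision),
      y = py[fid] + stats::rnorm(m, 0, loc_precision),
      intensity = brightness,
      channel = if (nrow(table)) table$channel[1] else 1L,
      fiducial = fid)
    base <- as.data.frame(table)
    if (is.null(base$fiducial)) base$fiducial <- NA_integer_
    for (col in setdiff(names(base), names(add))) add[[col]] <- NA
    for (col in setdiff(names(add), names(base))) base[[col]] <- NA
    out <- as_loc_table(rbind(base, add[, names(base)]))
    ids <- split(add$id, add$fiducial)
    list(table = out, fiducial_ids = ids)
  })
}
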