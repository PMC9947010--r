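#' Localization table
#'
#' The central data structure of the package: one row per fitted
#' single-molecule emission. A `loc_table` is a plain `data.frame` with
#' columns `id` (unique integer within the table), `frame` (0-based integer),
#' `x`, `y` (nanometres, image convention: origin top-left, y increasing
#' downward), and optionally `sigma` (SD of the Gaussian fit, nm),
#' `intensity` (photons) and `channel` (small integer, default 1). Unknown
#' extra columns are carried along untouched.
#'
#' @param frame 0-based integer frame index per localization.
#' @param x,y Coordinates in nm.
#' @param sigma Optional Gaussian-fit SD in nm.
#' @param intensity Optional photon count.
#' @param channel Channel index, default 1.
#' @param id Optional unique ids; generated sequentially if missing.
#' @param ... Extra per-localization columns kept as-is.
#' @return A `data.frame` of class `loc_table`, sorted by (channel, frame).
#' @examples
#' tab <- loc_table(frame = c(0, 0, 1), x = c(10, 500, 12), y = c(5, 5, 6))
#' nrow(tab)
#' @export
loc_table <- function(frame, x, y, sigma = NULL, intensity = NULL,
                      channel = 1L, id = NULL, ...) {
  n <- length(frame)
  stopifnot(length(x) == n, length(y) == n)
  if (n > 0 && (any(!is.finite(x)) || any(!is.finite(y)))) {
    stop("localization coordinates must be finite")
  }
  if (n > 0 && any(frame < 0)) stop("frames must be >= 0")
  if (is.null(id)) id <- seq_len(n)
  if (anyDuplicated(id)) stop("localization ids must be unique")
  df <- data.frame(id = as.integer(id), frame = as.integer(frame),
                   x = as.numeric(x), y = as.numeric(y))
  if (!is.null(sigma)) df$sigma <- as.numeric(sigma)
  if (!is.null(intensity)) df$intensity <- as.numeric(intensity)
  df$channel <- as.integer(rep_len(channel, n))
  extras <- list(...)
  for (nm in names(extras)) df[[nm]] <- extras[[nm]]
  as_loc_table(df)
}

#' Coerce a data.frame to a localization table
#'
#' Validates mandatory columns, fills defaults, and sorts by
#' (channel, frame).
#'
#' @param df A data.frame with at least `frame`, `x`, `y`.
#' @return A `loc_table`.
#' @export
as_loc_table <- function(df) {
  need <- c("frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(df$id)) df$id <- seq_len(nrow(df))
  if (is.null(df$channel)) df$channel <- 1L
  df <- df[order(df$channel, df$frame, df$id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("loc_table", "data.frame")
  df
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("<loc_table> %d localizations, %d channel(s), frames %s-%s\n",
              nrow(x), length(unique(x$channel)),
              if (nrow(x)) min(x$frame) else "-",
              if (nrow(x)) max(x$frame) else "-"))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L), ...)
  invisible(x)
}

# ThunderSTORM CSV header <-> internal column names
.ts_columns <- c(
  id = "id", frame = "frame", `x [nm]` = "x", `y [nm]` = "y",
  `sigma [nm]` = "sigma", `intensity [photon]` = "intensity",
  channel = "channel"
)

#' Read a ThunderSTORM-dialect localization CSV
#'
#' Accepts the header names `"id"`, `"frame"`, `"x [nm]"`, `"y [nm]"`,
#' `"sigma [nm]"`, `"intensity [photon]"`, `"channel"`. The minimal dialect
#' needs only `frame`, `x [nm]` and `y [nm]`; other columns default to
#' absent. Columns with unrecognised names are preserved as opaque extras.
#'
#' @param path CSV file path.
#' @param frames_one_based If `TRUE`, frames in the file are 1-based and are
#'   converted to the 0-based convention used internally.
#' @return A `loc_table`.
#' @export
read_localizations <- function(path, frames_one_based = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  known <- names(.ts_columns)
  hits <- intersect(known, names(df))
  mapped <- names(df)
  mapped[match(hits, names(df))] <- .ts_columns[hits]
  names(df) <- mapped
  miss <- setdiff(c("frame", "x", "y"), names(df))
  if (length(miss)) {
    stop("localization file lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!is.numeric(df$frame) || !is.numeric(df$x) || !is.numeric(df$y)) {
    stop("file does not look like a headed localization CSV")
  }
  if (frames_one_based) df$frame <- df$frame - 1L
  as_loc_table(df)
}

#' Write a localization table as ThunderSTORM-dialect CSV
#'
#' @param table A `loc_table`.
#' @param path Output path.
#' @param frames_one_based Write 1-based frames if `TRUE`.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, frames_one_based = FALSE) {
  df <- as.data.frame(table)
  if (frames_one_based) df$frame <- df$frame + 1L
  back <- stats::setNames(names(.ts_columns), .ts_columns)
  hits <- intersect(names(back), names(df))
  names(df)[match(hits, names(df))] <- back[hits]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Filter localizations by Gaussian-fit sigma
#'
#' Out-of-focus emissions are removed by discarding localizations whose
#' fitted PSF standard deviation exceeds `max_sigma` (default 200 nm).
#'
#' @param table A `loc_table` with a `sigma` column.
#' @param max_sigma Cutoff in nm; rows with `sigma <= max_sigma` are kept.
#' @return The filtered `loc_table`, with attribute `n_removed`.
#' @export
filter_sigma <- function(table, max_sigma = 200) {
  if (is.null(table$sigma)) stop("sigma column absent; cannot filter")
  keep <- table$sigma <= max_sigma
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Group localizations of one emitter across consecutive frames
#'
#' A blinking fluorophore that stays on for several frames produces one
#' localization per frame; left unmerged these inflate apparent clustering.
#' Localizations in consecutive frames (gap at most `max_frame_gap`) lying
#' within `max_distance` of an open chain's running centroid are merged into
#' one record at the unweighted centroid, timestamped with the first frame of
#' the chain and carrying the summed intensity. The default `max_distance`
#' is one camera pixel (160 nm) and the default trace length is unbounded.
#'
#' @param table A single-channel `loc_table`.
#' @param max_distance Merge radius in nm (default one 160-nm pixel).
#' @param max_frame_gap Maximum number of missed frames inside a chain
#'   (default `Inf`, i.e. trace length limited only by the acquisition).
#' @return A grouped `loc_table`; attribute `n_input` records the input size.
#' @export
group_localizations <- function(table, max_distance = 160,
                                max_frame_gap = Inf) {
  if (max_distance < 0) stop("max_distance must be non-negative")
  if (length(unique(table$channel)) > 1) {
    stop("grouping operates on a single channel")
  }
  n <- nrow(table)
  if (n == 0) return(table)
  ord <- order(table$frame, table$id)
  fr <- table$frame[ord]; xx <- table$x[ord]; yy <- table$y[ord]
  inten <- if (is.null(table$intensity)) rep(NA_real_, n) else
    table$intensity[ord]
  sig <- if (is.null(table$sigma)) rep(NA_real_, n) else table$sigma[ord]

  # open chains: running centroid, member count, first frame, last frame
  gx <- numeric(0); gy <- numeric(0); gn <- integer(0)
  gf <- integer(0); glast <- integer(0)
  gsumx <- numeric(0); gsumy <- numeric(0)
  gint <- numeric(0); gsig <- numeric(0)
  closed <- list()
  assign_row <- integer(n)

  frames <- unique(fr)
  rowptr <- 1L
  for (f in frames) {
    idx <- which(fr == f)
    # close chains that can no longer be extended
    if (length(gf)) {
      stale <- which(glast < f - 1L - max_frame_gap)
      if (length(stale)) {
        for (s in stale) {
          closed[[length(closed) + 1L]] <-
            c(gsumx[s] / gn[s], gsumy[s] / gn[s], gf[s], gint[s], gsig[s],
              gn[s])
        }
        keep <- setdiff(seq_along(gf), stale)
        gx <- gx[keep]; gy <- gy[keep]; gn <- gn[keep]; gf <- gf[keep]
        glast <- glast[keep]; gsumx <- gsumx[keep]; gsumy <- gsumy[keep]
        gint <- gint[keep]; gsig <- gsig[keep]
      }
    }
    open_ok <- which(glast >= f - 1L - max_frame_gap & glast < f)
    if (length(open_ok) && length(idx)) {
      d <- sqrt(outer(xx[idx], gx[open_ok], "-")^2 +
                outer(yy[idx], gy[open_ok], "-")^2)
      cand <- which(d <= max_distance, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        used_loc <- logical(length(idx)); used_grp <- logical(length(open_ok))
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (used_loc[i] || used_grp[j]) next
          used_loc[i] <- TRUE; used_grp[j] <- TRUE
          g <- open_ok[j]
          gsumx[g] <- gsumx[g] + xx[idx[i]]
          gsumy[g] <- gsumy[g] + yy[idx[i]]
          gn[g] <- gn[g] + 1L
          gx[g] <- gsumx[g] / gn[g]; gy[g] <- gsumy[g] / gn[g]
          glast[g] <- f
          gint[g] <- gint[g] + ifelse(is.na(inten[idx[i]]), 0, inten[idx[i]])
          gsig[g] <- gsig[g] + ifelse(is.na(sig[idx[i]]), 0, sig[idx[i]])
        }
        idx <- idx[!used_loc]
      }
    }
    # unmatched localizations open new chains
    for (i in idx) {
      gx <- c(gx, xx[i]); gy <- c(gy, yy[i]); gn <- c(gn, 1L)
      gf <- c(gf, f); glast <- c(glast, f)
      gsumx <- c(gsumx, xx[i]); gsumy <- c(gsumy, yy[i])
      gint <- c(gint, ifelse(is.na(inten[i]), 0, inten[i]))
      gsig <- c(gsig, ifelse(is.na(sig[i]), 0, sig[i]))
    }
  }
  for (s in seq_along(gf)) {
    closed[[length(closed) + 1L]] <-
      c(gsumx[s] / gn[s], gsumy[s] / gn[s], gf[s], gint[s], gsig[s], gn[s])
  }
  m <- do.call(rbind, closed)
  has_int <- !is.null(table$intensity)
  has_sig <- !is.null(table$sigma)
  out <- loc_table(frame = m[, 3], x = m[, 1], y = m[, 2],
                   sigma = if (has_sig) m[, 5] / m[, 6] else NULL,
                   intensity = if (has_int) m[, 4] else NULL,
                   channel = table$channel[1], n_merged = as.integer(m[, 6]))
  attr(out, "n_input") <- n
  out
}
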