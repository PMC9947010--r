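#' Two-Gaussian decomposition of an MJD histogram
#'
#' The distribution of per-track mean jump distances of a membrane protein
#' typically superimposes a low-mobility and a high-mobility population.
#' Following the curve-fitting workflow used on such histograms, the binned
#' counts are fitted by least squares with
#' `A1*exp(-(x-mu1)^2/(2*s1^2)) + A2*exp(-(x-mu2)^2/(2*s2^2))`,
#' initialised from the moments of the sub-samples below and above the
#' classification threshold (140 nm). Component areas are `A*s*sqrt(2*pi)`
#' and the high-mobility fraction is their ratio (see [r_value()]).
#'
#' A fit is flagged `degenerate` when either component carries less than 1%
#' of the total area or when the two means are closer than half the summed
#' SDs (the data do not support two components).
#'
#' @param mjds Numeric vector of MJDs (or a `trackset`).
#' @param bin_width,range Histogram geometry passed to [mjd_histogram()].
#' @param threshold Initialisation split in nm (default 140).
#' @param min_n Minimum number of MJDs required (default 200).
#' @param max_restarts Optimiser restarts with perturbed initialisation.
#' @return An object of class `two_gauss_fit`: list with `A_low`, `mu_low`,
#'   `s_low`, `A_high`, `mu_high`, `s_high`, `area_low`, `area_high`, `R`,
#'   `degenerate`, `convergence`, `sse`, `histogram`.
#' @export
fit_two_gaussians <- function(mjds, bin_width = 10, range = c(0, 400),
                              threshold = 140, min_n = 200,
                              max_restarts = 5) {
  if (inherits(mjds, "trackset")) mjds <- track_mjds(mjds)
  mjds <- mjds[!is.na(mjds)]
  if (length(mjds) < min_n) {
    stop("need at least ", min_n, " MJDs for a two-component fit")
  }
  h <- mjd_histogram(mjds, bin_width = bin_width, range = range)
  x <- h$mids
  y <- h$counts

  lo <- mjds[mjds < threshold]
  hi <- mjds[mjds >= threshold]
  init_comp <- function(v, fallback_mu) {
    if (length(v) >= 2) {
      c(n = length(v), mu = mean(v), s = max(stats::sd(v), bin_width / 2))
    } else {
      c(n = length(v), mu = fallback_mu, s = max(stats::sd(mjds),
                                                 bin_width))
    }
  }
  c1 <- init_comp(lo, threshold * 0.7)
  c2 <- init_comp(hi, threshold * 1.3)
  amp <- function(n, s) n * bin_width / (s * sqrt(2 * pi))
  p0 <- c(A1 = amp(c1["n"], c1["s"]), mu1 = unname(c1["mu"]),
          ls1 = log(unname(c1["s"])),
          A2 = amp(c2["n"], c2["s"]), mu2 = unname(c2["mu"]),
          ls2 = log(unname(c2["s"])))
  names(p0) <- c("A1", "mu1", "ls1", "A2", "mu2", "ls2")

  sse <- function(p) {
    m <- p["A1"] * exp(-(x - p["mu1"])^2 / (2 * exp(2 * p["ls1"]))) +
         p["A2"] * exp(-(x - p["mu2"])^2 / (2 * exp(2 * p["ls2"])))
    sum((y - m)^2)
  }
  lower <- c(0, range[1], log(bin_width / 10), 0, range[1],
             log(bin_width / 10))
  upper <- c(Inf, range[2], log(diff(range)), Inf, range[2],
             log(diff(range)))

  best <- NULL
  jitters <- list(c(1, 1, 1, 1, 1, 1), c(1.2, 0.9, 1, 0.8, 1.1, 1),
                  c(0.8, 1.1, 1.2, 1.2, 0.9, 0.8),
                  c(1, 0.8, 0.9, 1, 1.2, 1.1), c(1.5, 1, 1, 0.5, 1, 1),
                  c(0.5, 1.05, 1, 1.5, 0.95, 1))
  diag_log <- character(0)
  for (k in seq_len(min(max_restarts + 1, length(jitters)))) {
    pk <- p0 * jitters[[k]]
    pk <- pmin(pmax(pk, lower + 1e-9), upper - 1e-9)
    fit <- tryCatch(
      stats::optim(pk, sse, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 2000)),
      error = function(e) NULL)
    if (is.null(fit)) {
      diag_log <- c(diag_log, sprintf("restart %d: optim error", k))
      next
    }
    diag_log <- c(diag_log,
                  sprintf("restart %d: convergence=%d sse=%.4g", k,
                          fit$convergence, fit$value))
    if (fit$convergence == 0 &&
        (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("two-Gaussian fit failed to converge after restarts:\n",
         paste(diag_log, collapse = "\n"))
  }
  p <- best$par
  comps <- list(c(A = unname(p["A1"]), mu = unname(p["mu1"]),
                  s = exp(unname(p["ls1"]))),
                c(A = unname(p["A2"]), mu = unname(p["mu2"]),
                  s = exp(unname(p["ls2"]))))
  if (comps[[1]]["mu"] > comps[[2]]["mu"]) comps <- rev(comps)
  a_low <- comps[[1]]["A"] * comps[[1]]["s"] * sqrt(2 * pi)
  a_high <- comps[[2]]["A"] * comps[[2]]["s"] * sqrt(2 * pi)
  tot <- a_low + a_high
  sep <- comps[[2]]["mu"] - comps[[1]]["mu"]
  degenerate <- tot <= 0 || min(a_low, a_high) < 0.01 * tot ||
    sep < 0.5 * (comps[[1]]["s"] + comps[[2]]["s"])
  structure(list(
    A_low = unname(comps[[1]]["A"]), mu_low = unname(comps[[1]]["mu"]),
    s_low = unname(comps[[1]]["s"]),
    A_high = unname(comps[[2]]["A"]), mu_high = unname(comps[[2]]["mu"]),
    s_high = unname(comps[[2]]["s"]),
    area_low = unname(a_low), area_high = unname(a_high),
    R = unname(a_high / tot),
    threshold = threshold, degenerate = unname(degenerate),
    convergence = best$convergence, sse = best$value,
    diagnostics = diag_log, histogram = h), class = "two_gauss_fit")
}

#' @export
print.two_gauss_fit <- function(x, ...) {
  cat(sprintf(
    "<two_gauss_fit> mu_low=%.1f nm (s=%.1f), mu_high=%.1f nm (s=%.1f)\n",
    x$mu_low, x$s_low, x$mu_high, x$s_high))
  cat(sprintf("  R = %.3f (high-mobility area fraction)%s\n", x$R,
              if (x$degenerate) "  [DEGENERATE]" else ""))
  invisible(x)
}

#' High-mobility area fraction (R-value) of a two-Gaussian fit
#'
#' `R = area_high / (area_low + area_high)` with component areas
#' `A * s * sqrt(2*pi)`.
#'
#' @param fit A `two_gauss_fit`.
#' @param force Return R even for a degenerate fit.
#' @return The fraction in `[0, 1]`.
#' @export
r_value <- function(fit, force = FALSE) {
  stopifnot(inherits(fit, "two_gauss_fit"))
  if (fit$degenerate && !force) {
    stop("fit is degenerate; pass force = TRUE to extract R anyway")
  }
  fit$R
}

#' Sample-level EM cross-check of the two-Gaussian decomposition
#'
#' Plain two-component Gaussian mixture EM on the raw MJDs, offered as an
#' independent check of the histogram least-squares route. Component weights
#' play the role of the area fractions.
#'
#' @param mjds Numeric MJDs.
#' @param threshold Initialisation split (default 140 nm).
#' @param max_iter,tol EM controls.
#' @return List with `mu`, `s`, `weight` (each length 2, low first) and
#'   `R` (weight of the high component).
#' @export
fit_two_gaussians_em <- function(mjds, threshold = 140, max_iter = 500,
                                 tol = 1e-8) {
  mjds <- mjds[!is.na(mjds)]
  mu <- c(mean(mjds[mjds < threshold]), mean(mjds[mjds >= threshold]))
  if (anyNA(mu)) mu <- stats::quantile(mjds, c(0.25, 0.75), names = FALSE)
  s <- rep(max(stats::sd(mjds) / 2, 1e-6), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(mjds, mu[1], s[1])
    d2 <- w[2] * stats::dnorm(mjds, mu[2], s[2])
    tot <- d1 + d2 + 1e-300
    g <- d1 / tot
    w <- c(mean(g), mean(1 - g))
    mu <- c(sum(g * mjds) / sum(g), sum((1 - g) * mjds) / sum(1 - g))
    s <- sqrt(c(sum(g * (mjds - mu[1])^2) / sum(g),
                sum((1 - g) * (mjds - mu[2])^2) / sum(1 - g)))
    s <- pmax(s, 1e-6)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu); s <- rev(s); w <- rev(w)
  }
  list(mu = mu, s = s, weight = w, R = w[2])
}
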