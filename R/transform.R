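#' 2D affine transform
#'
#' Chromatic aberration between sequentially imaged channels is modelled as
#' an affine map `p -> A p + b` fitted on multicolour bead positions.
#'
#' @param A 2x2 linear part (must be invertible).
#' @param b Length-2 translation in nm.
#' @return An object of class `affine2d`.
#' @export
affine_transform <- function(A = diag(2), b = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  if (abs(det(A)) <= 1e-12) stop("linear part is singular")
  structure(list(A = A, b = as.numeric(b)), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d>\n  A = [", sprintf("%.6g", t(x$A)), "]\n  b = (",
      sprintf("%.6g", x$b), ") nm\n")
  invisible(x)
}

#' Fit an affine channel transform from matched bead positions
#'
#' Least-squares fit of `t(A_i) = B_i` over matched pairs (e.g. TetraSpeck
#' beads seen in both channels). Requires at least 3 non-collinear pairs.
#'
#' @param pointsA,pointsB n x 2 matrices of matched positions (nm).
#' @return An `affine2d` with attribute `rms` (residual RMS in nm).
#' @export
fit_channel_transform <- function(pointsA, pointsB) {
  pointsA <- as.matrix(pointsA); pointsB <- as.matrix(pointsB)
  n <- nrow(pointsA)
  if (n != nrow(pointsB)) stop("point sets must be matched (equal rows)")
  if (n < 3) stop("need at least 3 matched pairs")
  X <- cbind(pointsA, 1)
  if (qr(X)$rank < 3) stop("matched pairs are collinear")
  beta <- qr.solve(X, pointsB)        # 3 x 2: rows (a1., a2., b)
  A <- t(beta[1:2, , drop = FALSE])
  b <- as.numeric(beta[3, ])
  tr <- affine_transform(A, b)
  fit <- X %*% beta
  attr(tr, "rms") <- sqrt(mean(rowSums((fit - pointsB)^2)))
  tr
}

#' Apply an affine transform to a localization table
#'
#' @param table A `loc_table`.
#' @param transform An `affine2d`.
#' @param inverse Apply the inverse map instead.
#' @return The transformed table.
#' @export
apply_transform <- function(table, transform, inverse = FALSE) {
  p <- rbind(table$x, table$y)
  if (inverse) {
    q <- solve(transform$A, p - transform$b)
  } else {
    q <- transform$A %*% p + transform$b
  }
  table$x <- q[1, ]
  table$y <- q[2, ]
  table
}

#' Read / write an affine transform as 6 numbers
#'
#' Plain-text: `a11 a12 a21 a22 bx by` on one line.
#'
#' @param path File path.
#' @param transform An `affine2d`.
#' @return `read_transform` returns an `affine2d`.
#' @export
read_transform <- function(path) {
  v <- scan(path, quiet = TRUE)
  if (length(v) != 6) stop("transform file must contain exactly 6 numbers")
  affine_transform(matrix(v[1:4], 2, 2, byrow = TRUE), v[5:6])
}

#' @rdname read_transform
#' @export
write_transform <- function(transform, path) {
  writeLines(paste(c(t(transform$A), transform$b), collapse = " "), path)
  invisible(path)
}
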