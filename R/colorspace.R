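# sRGB <-> CIE Lab conversions and the colour distances used throughout.
# All conversions assume 8-bit sRGB, D65 reference white, 2 degree observer.

# sRGB (linear) -> XYZ matrix, D65
.srgb2xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

.white_d65 <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

#' Convert 8-bit sRGB colours to CIE Lab
#'
#' Standard sRGB companding (piecewise transfer function), linear RGB to XYZ
#' under D65, then the CIE 1976 L*a*b* transform. Vectorized over rows.
#'
#' @param rgb Numeric vector of length 3 or matrix with 3 columns (r, g, b),
#'   integer channel values in `[0, 255]`.
#' @return Matrix with columns `L`, `a`, `b`; `L` in `[0, 100]`.
#' @examples
#' srgb_to_lab(c(255, 0, 0))
#' @export
srgb_to_lab <- function(rgb) {
  rgb <- .as_rgb_matrix(rgb)
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb2xyz)
  xyz_n <- sweep(xyz, 2, .white_d65, "/")
  eps <- (6 / 29)^3
  f <- ifelse(xyz_n > eps, xyz_n^(1 / 3), xyz_n / (3 * (6 / 29)^2) + 4 / 29)
  out <- cbind(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3])
  )
  out
}

#' Convert CIE Lab colours to 8-bit sRGB
#'
#' Inverse of [srgb_to_lab()]. Out-of-gamut colours are clipped channel-wise
#' to `[0, 255]`; channels are rounded to integers.
#'
#' @param lab Numeric vector of length 3 or matrix with 3 columns (L, a, b).
#' @return Integer matrix with columns `r`, `g`, `b` in `[0, 255]`.
#' @export
lab_to_srgb <- function(lab) {
  lab <- .as_lab_matrix(lab)
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  finv <- function(t) ifelse(t > 6 / 29, t^3, 3 * (6 / 29)^2 * (t - 4 / 29))
  xyz <- cbind(finv(fx), finv(fy), finv(fz))
  xyz <- sweep(xyz, 2, .white_d65, "*")
  lin <- xyz %*% t(solve(.srgb2xyz))
  lin <- pmin(pmax(lin, 0), 1)
  v <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  out <- round(pmin(pmax(v, 0), 1) * 255)
  colnames(out) <- c("r", "g", "b")
  storage.mode(out) <- "integer"
  out
}

#' Colour distances in CIE Lab space
#'
#' `delta_e()` is the CIE76 colour difference (plain Euclidean norm over
#' L, a, b). `chromatic_distance()` is the Euclidean norm over the opponent
#' axes (a, b) only, and `achromatic_distance()` is `|delta L|`, so that
#' `delta_e^2 = chromatic^2 + achromatic^2`.
#'
#' @param x,y Lab colours: vectors of length 3 or matrices with 3 columns
#'   (rows are paired, recycling a single row).
#' @return Numeric vector of distances.
#' @export
delta_e <- function(x, y) {
  d <- .lab_pair_diff(x, y)
  sqrt(rowSums(d^2))
}

#' @rdname delta_e
#' @export
chromatic_distance <- function(x, y) {
  d <- .lab_pair_diff(x, y)
  sqrt(d[, 2]^2 + d[, 3]^2)
}

#' @rdname delta_e
#' @export
achromatic_distance <- function(x, y) {
  d <- .lab_pair_diff(x, y)
  abs(d[, 1])
}

#' Pairwise CIE76 distance matrix for a Lab palette
#'
#' @param lab Matrix with 3 columns (L, a, b), one colour per row.
#' @param which One of `"full"` (ΔE), `"chromatic"` (a, b only) or
#'   `"achromatic"` (`|delta L|`).
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
delta_e_matrix <- function(lab, which = c("full", "chromatic", "achromatic")) {
  which <- match.arg(which)
  lab <- .as_lab_matrix(lab)
  cols <- switch(which, full = 1:3, chromatic = 2:3, achromatic = 1)
  m <- lab[, cols, drop = FALSE]
  d <- as.matrix(stats::dist(m))
  dimnames(d) <- NULL
  d
}

.as_rgb_matrix <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = TRUE)
  rgb <- as.matrix(rgb)
  if (ncol(rgb) != 3) stop("rgb must have 3 channels")
  if (anyNA(rgb) || any(rgb < 0) || any(rgb > 255))
    stop("rgb channels must lie in [0, 255]")
  rgb
}

.as_lab_matrix <- function(lab) {
  if (is.null(dim(lab))) lab <- matrix(lab, ncol = 3, byrow = TRUE)
  lab <- as.matrix(lab)
  if (ncol(lab) != 3) stop("lab must have 3 columns (L, a, b)")
  if (anyNA(lab) || any(!is.finite(lab))) stop("lab values must be finite")
  lab
}

.lab_pair_diff <- function(x, y) {
  x <- .as_lab_matrix(x)
  y <- .as_lab_matrix(y)
  if (nrow(x) == 1 && nrow(y) > 1) x <- x[rep(1, nrow(y)), , drop = FALSE]
  if (nrow(y) == 1 && nrow(x) > 1) y <- y[rep(1, nrow(x)), , drop = FALSE]
  if (nrow(x) != nrow(y)) stop("x and y must have matching numbers of rows")
  x - y
}
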