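# Image-moment features on key frames.
#
# Coordinate convention (fixed across the codebase): x = column index,
# y = row index, both 0-based, intensity I(x, y) = pixel value. Key
# frames derived from differences (KF2) can be signed; moments are
# computed on the signed intensities as-is, with a guard on |M00| that
# defines a degenerate all-zero branch so NaN/Inf are never emitted.

#' Raw image moment
#'
#' `M_pq = sum_{x,y} x^p y^q I(x,y)` over a 2-D grid, with `x` the
#' column and `y` the row, both 0-based.
#'
#' @param grid numeric matrix (rows = y, columns = x).
#' @param p,q non-negative integer orders.
#' @return the raw moment, a single number.
#' @export
raw_moment <- function(grid, p, q) {
  grid <- as.matrix(grid)
  stopifnot(p >= 0, q >= 0)
  x <- matrix(rep(seq_len(ncol(grid)) - 1, each = nrow(grid)), nrow = nrow(grid))
  y <- matrix(rep(seq_len(nrow(grid)) - 1, times = ncol(grid)), nrow = nrow(grid))
  sum(x^p * y^q * grid)
}

#' Second-order central moments and Hu's seven moment invariants
#'
#' Computes the three second-order central moments `mu20, mu11, mu02`
#' about the intensity centroid, plus Hu's seven invariants from the
#' normalized central moments `eta_pq = mu_pq / |mu00|^(1 + (p+q)/2)`.
#' The absolute value in the normalization keeps the invariants real
#' for signed grids (difference key frames can have negative total
#' mass).
#'
#' If the total mass is degenerate (`|M00| <= eps` with
#' `eps = 1e-12 * max|I|`, floored at `1e-12`) the centroid is
#' undefined and all ten outputs are 0 by convention.
#'
#' @param grid numeric matrix (rows = y, columns = x).
#' @return named numeric vector of length 10:
#'   `mu20, mu11, mu02, hu1..hu7`.
#' @export
central_and_hu <- function(grid) {
  grid <- as.matrix(grid)
  out_names <- c("mu20", "mu11", "mu02", paste0("hu", 1:7))
  m00 <- sum(grid)
  eps <- max(1e-12, 1e-12 * max(abs(grid)))
  if (abs(m00) <= eps) {
    return(stats::setNames(numeric(10), out_names))
  }
  x <- matrix(rep(seq_len(ncol(grid)) - 1, each = nrow(grid)), nrow = nrow(grid))
  y <- matrix(rep(seq_len(nrow(grid)) - 1, times = ncol(grid)), nrow = nrow(grid))
  xbar <- sum(x * grid) / m00
  ybar <- sum(y * grid) / m00
  dx <- x - xbar
  dy <- y - ybar
  mu <- function(p, q) sum(dx^p * dy^q * grid)
  mu20 <- mu(2, 0); mu11 <- mu(1, 1); mu02 <- mu(0, 2)
  eta <- function(m, p, q) m / abs(m00)^(1 + (p + q) / 2)
  n20 <- eta(mu20, 2, 0); n11 <- eta(mu11, 1, 1); n02 <- eta(mu02, 0, 2)
  n30 <- eta(mu(3, 0), 3, 0); n21 <- eta(mu(2, 1), 2, 1)
  n12 <- eta(mu(1, 2), 1, 2); n03 <- eta(mu(0, 3), 0, 3)
  hu <- c(
    n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2))
  stats::setNames(c(mu20, mu11, mu02, hu), out_names)
}

#' Feature vector of a key-frame set
#'
#' Concatenates [central_and_hu()] over the eight key frames in the
#' fixed order `KF1..KF8 x [mu20, mu11, mu02, hu1..hu7]`, yielding the
#' 80 features of one analysis window. Feature index `f` (1-80) refers
#' to this ordering throughout the package.
#'
#' @param kfs a `keyframe_set`.
#' @return named numeric vector of length 80 (`KF1_mu20 .. KF8_hu7`).
#' @export
features_from_keyframes <- function(kfs) {
  stopifnot(inherits(kfs, "keyframe_set"))
  out <- numeric(0)
  for (k in rownames(kfs)) {
    v <- central_and_hu(keyframe_grid(kfs, k))
    names(v) <- paste0(k, "_", names(v))
    out <- c(out, v)
  }
  stopifnot(length(out) == 80L, all(is.finite(out)))
  out
}

#' Names of the 80 window features
#'
#' @return character vector of length 80, `KF1_mu20` .. `KF8_hu7`, in
#'   feature-index order.
#' @export
feature_names <- function() {
  as.vector(outer(c("mu20", "mu11", "mu02", paste0("hu", 1:7)),
                  paste0("KF", 1:8),
                  function(m, k) paste0(k, "_", m)))
}

#' All 80 features of one window
#'
#' Convenience wrapper: key frames then image moments.
#'
#' @param window a `tpm_window` (or frames matrix).
#' @return named numeric vector of length 80.
#' @export
window_features <- function(window) {
  features_from_keyframes(compute_keyframes(window))
}
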