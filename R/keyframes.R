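#' Reduce a window to its eight key frames
#'
#' Key frames compress the temporal dimension of a window of pressure
#' frames `F(t)` into eight 2x10 grids that capture the pixel-wise
#' changes during the window:
#'
#' * `KF1` — per-pixel mean of all frames.
#' * `KF2` — per-pixel sum of successive differences
#'   `sum_t (F(t+1) - F(t))`; by telescoping this equals
#'   `F(last) - F(first)` and may be negative.
#' * `KF3` — per-pixel sum of the positive successive differences.
#' * `KF4` — magnitude of the per-pixel sum of the negative successive
#'   differences, so `KF3 - KF4 = KF2` elementwise.
#' * `KF5` / `KF6` — the frame with the maximum / minimum mean pixel
#'   value (earliest frame on ties).
#' * `KF7` — the frame with the maximum pixel standard deviation
#'   (earliest on ties).
#' * `KF8` — per-pixel mean of the thresholded frames `Fp(t)` in which
#'   pixels strictly below the frame's own mean are zeroed (pixels equal
#'   to the mean are kept); the divisor is the full frame count.
#'
#' @param window a `tpm_window`, or a plain numeric matrix of frames
#'   (one row per frame, 20 pixel columns).
#' @return object of class `keyframe_set`: an 8x20 numeric matrix with
#'   rows `KF1..KF8` and the canonical pixel columns.
#' @export
compute_keyframes <- function(window) {
  X <- if (inherits(window, "tpm_window")) window$frames else as.matrix(window)
  if (nrow(X) < 2L) stop("window too short: need at least 2 frames")
  D <- diff(X)
  fmeans <- rowMeans(X)
  fsds <- apply(X, 1, stats::sd)
  kf <- rbind(
    KF1 = colMeans(X),
    KF2 = colSums(D),
    KF3 = colSums(pmax(D, 0)),
    KF4 = abs(colSums(pmin(D, 0))),
    KF5 = X[which.max(fmeans), ],
    KF6 = X[which.min(fmeans), ],
    KF7 = X[which.max(fsds), ],
    KF8 = colMeans(X * (X >= fmeans)))
  colnames(kf) <- pixel_cols()
  structure(kf, class = c("keyframe_set", "matrix", "array"))
}

#' Reshape one key frame into its 2x10 sensor-grid layout
#'
#' @param kfs a `keyframe_set`.
#' @param which key frame name (`"KF1"`..`"KF8"`) or index 1-8.
#' @return a 2x10 numeric matrix (rows = sensor rows, columns along the
#'   forehead).
#' @export
keyframe_grid <- function(kfs, which = "KF1") {
  v <- kfs[which, ]
  matrix(v, nrow = 2, ncol = 10, byrow = TRUE,
         dimnames = list(c("r1", "r2"), paste0("c", 1:10)))
}
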