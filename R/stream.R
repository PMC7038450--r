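#' Construct a pressure-frame stream
#'
#' A frame stream is the raw output of the 2x10 textile pressure-mapping
#' (TPM) headband: a time-ordered sequence of frames, each holding 20
#' analog-to-digital converter (ADC) counts. The scanner samples at a
#' nominal 15 ms interval (about 66.7 frames per second); timestamps are
#' integer milliseconds and jitter is tolerated, no resampling is done.
#'
#' @param t_ms integer vector of frame timestamps in milliseconds,
#'   strictly increasing.
#' @param values numeric matrix with one row per frame and 20 columns in
#'   the canonical pixel order `r1c1..r1c10, r2c1..r2c10` (row 1 and
#'   row 2 of the sensor array, columns running along the forehead).
#' @param nominal_period nominal sampling period in milliseconds.
#' @param raw if `TRUE` (the default for sensor data) values must be
#'   integers in `[0, 4095]` (12-bit ADC counts). Derived streams may be
#'   real-valued and signed.
#'
#' @return An object of class `frame_stream`: a list with elements
#'   `t_ms`, `values` and attribute-like fields `nominal_period`, `raw`.
#' @export
frame_stream <- function(t_ms, values, nominal_period = 15L, raw = TRUE) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- matrix(values, nrow = length(t_ms), byrow = TRUE)
  if (ncol(values) != 20L) {
    stop("a frame has 2x10 = 20 pixels; got ", ncol(values), " columns")
  }
  if (length(t_ms) != nrow(values)) {
    stop("t_ms length (", length(t_ms), ") != number of frames (", nrow(values), ")")
  }
  if (length(t_ms) == 0L) stop("empty stream")
  t_ms <- as.numeric(t_ms)
  if (any(diff(t_ms) <= 0)) {
    bad <- which(diff(t_ms) <= 0)[1] + 1L
    stop("non-monotonic timestamp at frame ", bad)
  }
  if (raw) {
    if (any(values < 0 | values > ADC_MAX)) {
      stop("raw ADC values must lie in [0, ", ADC_MAX, "]")
    }
  }
  colnames(values) <- pixel_cols()
  structure(
    list(t_ms = t_ms, values = values,
         nominal_period = as.numeric(nominal_period), raw = isTRUE(raw)),
    class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("<frame_stream> %d frames, t = [%g, %g] ms, %g ms nominal period\n",
              length(x$t_ms), x$t_ms[1], x$t_ms[length(x$t_ms)], x$nominal_period))
  invisible(x)
}

#' Number of frames in a stream
#' @param stream a `frame_stream`.
#' @return integer frame count.
#' @export
n_frames <- function(stream) length(stream$t_ms)

#' Read a pressure stream from CSV
#'
#' The stream dialect is a plain UTF-8 CSV with header
#' `t_ms,r1c1..r1c10,r2c1..r2c10`, one frame per row, integer
#' millisecond timestamps and integer ADC counts.
#'
#' @param path file path.
#' @param raw enforce the raw 12-bit ADC range (default `TRUE`).
#' @return a `frame_stream`.
#' @export
read_stream <- function(path, raw = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  expected <- c("t_ms", pixel_cols())
  if (!identical(names(df), expected)) {
    stop("malformed stream header in ", path,
         "; expected t_ms,r1c1..r1c10,r2c1..r2c10")
  }
  if (nrow(df) == 0L) stop("empty stream file: ", path)
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop("malformed row at line ", bad + 1L, " in ", path)
    }
  }
  if (anyNA(df)) {
    bad <- which(rowSums(is.na(df)) > 0)[1]
    stop("malformed row at line ", bad + 1L, " in ", path)
  }
  t_ms <- df[[1]]
  if (any(diff(t_ms) <= 0)) {
    bad <- which(diff(t_ms) <= 0)[1] + 1L
    stop("non-monotonic timestamp at line ", bad + 1L, " in ", path)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (raw && any(vals < 0 | vals > ADC_MAX)) {
    bad <- which(rowSums(vals < 0 | vals > ADC_MAX) > 0)[1]
    stop("out-of-range ADC value at line ", bad + 1L, " in ", path)
  }
  frame_stream(t_ms, vals, raw = raw)
}

#' Write a pressure stream to CSV
#'
#' Writes the dialect read by [read_stream()]; the round trip is
#' value-exact for integer streams.
#'
#' @param stream a `frame_stream`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "frame_stream"))
  if (length(stream$t_ms) == 0L) stop("empty stream")
  df <- data.frame(t_ms = stream$t_ms, stream$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-frame mean pressure
#'
#' The arithmetic mean of the 20 pixels of every frame — the coarse
#' one-dimensional summary usually plotted alongside stimulus/input
#' events.
#'
#' @param stream a `frame_stream`.
#' @return a data.frame with columns `t_ms` and `mean_pressure`, one row
#'   per frame.
#' @export
mean_pressure_series <- function(stream) {
  stopifnot(inherits(stream, "frame_stream"))
  data.frame(t_ms = stream$t_ms, mean_pressure = rowMeans(stream$values))
}
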