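# Windowing of frame streams for the two experiment protocols.

new_window <- function(start, end, t_ms, frames, label, source) {
  if (length(t_ms) == 0L) stop("window [", start, ", ", end, "] contains no frames")
  structure(
    list(start = start, end = end, t_ms = t_ms, frames = frames,
         label = label, source = source),
    class = "tpm_window")
}

#' @export
print.tpm_window <- function(x, ...) {
  cat(sprintf("<tpm_window> [%g, %g] ms, %d frames, source=%s\n",
              x$start, x$end, length(x$t_ms), x$source))
  invisible(x)
}

#' Segment a stream by mimicking trials
#'
#' One analysis window per trial, wider than the held-expression period
#' so that the transition from the neutral face is covered: the window
#' starts at the midpoint between the 'next' click (stimulus shown) and
#' the 'record' click (expression affirmed), and ends 1 s after the end
#' of the two-second recording countdown.
#'
#' @param stream a `frame_stream` covering all trials.
#' @param log a `mimic_trial_log`.
#' @return list of `tpm_window` objects, one per trial, each labelled
#'   with the trial's stimulus metadata.
#' @export
segment_mimic <- function(stream, log) {
  stopifnot(inherits(stream, "frame_stream"), inherits(log, "mimic_trial_log"))
  t <- stream$t_ms
  out <- vector("list", nrow(log))
  for (i in seq_len(nrow(log))) {
    start <- (log$t_next[i] + log$t_record[i]) / 2
    end <- log$t_record_end[i] + 1000
    if (start < t[1] || end > t[length(t)]) {
      stop("trial ", i, " window [", start, ", ", end,
           "] falls outside the stream time range")
    }
    idx <- which(t >= start & t <= end)
    out[[i]] <- new_window(
      start, end, t[idx], stream$values[idx, , drop = FALSE],
      label = list(stimulus_id = log$stimulus_id[i],
                   stimulus_kind = log$stimulus_kind[i],
                   eyebrow = log$eyebrow[i], emotion = log$emotion[i]),
      source = "mimic")
  }
  out
}

#' Segment a stream into inter-stimulus windows
#'
#' One window between every two consecutive N-back stimuli, half-open
#' `[t_i, t_{i+1})` so each frame belongs to exactly one window. Each
#' window carries the four stimulus/input bits of its opening stimulus
#' (`s_audio`, `s_position`) and of any keypress falling inside the
#' window (`i_audio`, `i_position`), plus the derived condition flags
#' C1-C8 (see [label_window()]). The tail after the final stimulus has
#' no closing stimulus and is discarded.
#'
#' @param stream a `frame_stream` covering the session.
#' @param log an `nback_event_log`.
#' @return list of `tpm_window` objects, `nrow(stimuli) - 1` of them.
#' @export
segment_interstimulus <- function(stream, log) {
  stopifnot(inherits(stream, "frame_stream"), inherits(log, "nback_event_log"))
  st <- log$stimuli
  if (nrow(st) < 2L) stop("need at least 2 stimuli to form a window")
  t <- stream$t_ms
  out <- vector("list", nrow(st) - 1L)
  for (i in seq_len(nrow(st) - 1L)) {
    start <- st$t_ms[i]
    end <- st$t_ms[i + 1L]
    idx <- which(t >= start & t < end)
    bits <- window_bits(log, start, end)
    lab <- c(list(session_index = log$session_index, n_level = log$n_level,
                  window_index = i),
             bits,
             list(conditions = label_window(bits$s_audio, bits$s_position,
                                            bits$i_audio, bits$i_position)))
    out[[i]] <- new_window(start, end, t[idx], stream$values[idx, , drop = FALSE],
                           label = lab, source = "nback")
  }
  out
}

# Stimulus bits of the window-opening stimulus plus input presence bits;
# at most one input per channel is counted, later duplicates are ignored.
window_bits <- function(log, start, end) {
  i0 <- which(log$stimuli$t_ms == start)
  inp <- log$inputs[log$inputs$t_ms >= start & log$inputs$t_ms < end, , drop = FALSE]
  for (ch in c("audio", "position")) {
    k <- sum(inp$channel == ch)
    if (k > 1) warning("ignoring ", k - 1, " duplicate '", ch, "' input(s) in window [",
                       start, ", ", end, ")")
  }
  list(s_audio = as.integer(log$stimuli$s_audio[i0]),
       s_position = as.integer(log$stimuli$s_position[i0]),
       i_audio = as.integer(any(inp$channel == "audio")),
       i_position = as.integer(any(inp$channel == "position")))
}
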