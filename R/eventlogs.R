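#' Construct a mimicking-trial log
#'
#' One row per stimulus trial of the instructed-mimicking experiment.
#' The stimulus program shows a figure when the participant clicks
#' 'next' (`t_next`), the participant mimics it and clicks 'record'
#' (`t_record`), and a two-second countdown ends at `t_record_end`.
#'
#' @param trials data.frame with columns `t_next`, `t_record`,
#'   `t_record_end` (ms), `stimulus_id` (character), `eyebrow`
#'   (`"Neutral"`, `"Lower"`, `"Raise"` or `NA`), `emotion` (one of the
#'   seven basic emotions or `NA`), `stimulus_kind` (`"basic"` or
#'   `"portrait"`).
#' @return object of class `mimic_trial_log` (a validated data.frame).
#' @export
mimic_trial_log <- function(trials) {
  need <- c("t_next", "t_record", "t_record_end",
            "stimulus_id", "eyebrow", "emotion", "stimulus_kind")
  if (!all(need %in% names(trials))) {
    stop("missing trial columns: ", paste(setdiff(need, names(trials)), collapse = ", "))
  }
  trials <- as.data.frame(trials)[, need]
  if (nrow(trials) == 0L) stop("empty trial log")
  with_ord <- trials$t_next < trials$t_record & trials$t_record < trials$t_record_end
  if (!all(with_ord)) {
    stop("trial ", which(!with_ord)[1], ": timestamps must satisfy t_next < t_record < t_record_end")
  }
  if (any(trials$t_record_end - trials$t_record != 2000)) {
    bad <- which(trials$t_record_end - trials$t_record != 2000)[1]
    stop("trial ", bad, ": recording period must be the 2000 ms countdown")
  }
  if (nrow(trials) > 1L) {
    if (any(trials$t_next[-1] < trials$t_record_end[-nrow(trials)])) {
      stop("trials overlap or are out of order")
    }
  }
  if (!all(trials$stimulus_kind %in% c("basic", "portrait"))) {
    stop("stimulus_kind must be 'basic' or 'portrait'")
  }
  class(trials) <- c("mimic_trial_log", "data.frame")
  trials
}

#' Construct a dual N-back session event log
#'
#' Events of one dual (position + audio) N-back session: stimulus pairs
#' every ~3 s, each flagged with ground-truth positivity bits (whether
#' it matches the stimulus N steps earlier on that channel), and the
#' participant's keypress inputs per channel.
#'
#' @param session_index integer 1-9, position in the session schedule.
#' @param n_level N-back depth, 2 or 3.
#' @param stimuli data.frame with columns `t_ms`, `s_audio`,
#'   `s_position` (bits in `{0, 1}`); 21-24 rows, time-ordered.
#' @param inputs data.frame with columns `t_ms` and `channel`
#'   (`"audio"` or `"position"`); may be empty.
#' @param score optional pre-computed session score in `[0, 1]`.
#' @return object of class `nback_event_log`.
#' @export
nback_event_log <- function(session_index, n_level, stimuli, inputs =
                              data.frame(t_ms = numeric(), channel = character()),
                            score = NA_real_) {
  stopifnot(n_level %in% c(2L, 3L))
  stimuli <- as.data.frame(stimuli)[, c("t_ms", "s_audio", "s_position")]
  inputs <- as.data.frame(inputs)[, c("t_ms", "channel"), drop = FALSE]
  if (nrow(stimuli) < 2L) stop("a session needs at least 2 stimuli")
  if (any(diff(stimuli$t_ms) <= 0)) stop("stimuli must be strictly time-ordered")
  if (!all(unlist(stimuli[, c("s_audio", "s_position")]) %in% c(0, 1))) {
    stop("stimulus bits must be 0/1")
  }
  if (nrow(inputs) > 0 && !all(inputs$channel %in% c("audio", "position"))) {
    stop("input channel must be 'audio' or 'position'")
  }
  structure(
    list(session_index = as.integer(session_index), n_level = as.integer(n_level),
         stimuli = stimuli, inputs = inputs, score = score),
    class = "nback_event_log")
}

#' @export
print.nback_event_log <- function(x, ...) {
  cat(sprintf("<nback_event_log> session %d, %d-back, %d stimuli, %d inputs\n",
              x$session_index, x$n_level, nrow(x$stimuli), nrow(x$inputs)))
  invisible(x)
}

# --- event-per-row CSV serialization ---------------------------------------
# Both logs share one dialect: t_ms,event_type,payload with semicolon-packed
# payload fields. Writers are deterministic.

#' Write a mimicking-trial log to CSV
#'
#' Event rows `t_ms,event_type,payload`: one `next` event per trial
#' carrying `stimulus_id;stimulus_kind;eyebrow;emotion`, then `record`
#' and `record_end` events with empty payloads.
#'
#' @param log a `mimic_trial_log`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mimic_log <- function(log, path) {
  stopifnot(inherits(log, "mimic_trial_log"))
  blank <- function(x) ifelse(is.na(x), "", as.character(x))
  ev <- rbind(
    data.frame(t_ms = log$t_next, event_type = "next",
               payload = paste(blank(log$stimulus_id), log$stimulus_kind,
                               blank(log$eyebrow), blank(log$emotion), sep = ";")),
    data.frame(t_ms = log$t_record, event_type = "record", payload = ""),
    data.frame(t_ms = log$t_record_end, event_type = "record_end", payload = ""))
  ev <- ev[order(ev$t_ms, match(ev$event_type, c("next", "record", "record_end"))), ]
  utils::write.csv(ev, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a mimicking-trial log from CSV
#' @param path file written by [write_mimic_log()].
#' @return a `mimic_trial_log`.
#' @export
read_mimic_log <- function(path) {
  ev <- utils::read.csv(path, colClasses = c("numeric", "character", "character"))
  nexts <- ev[ev$event_type == "next", ]
  recs <- ev[ev$event_type == "record", ]
  ends <- ev[ev$event_type == "record_end", ]
  if (nrow(nexts) != nrow(recs) || nrow(recs) != nrow(ends)) {
    stop("unpaired trial events in ", path)
  }
  pay <- strsplit(nexts$payload, ";", fixed = TRUE)
  field <- function(i) vapply(pay, function(p) if (length(p) >= i) p[i] else "", "")
  na_if_empty <- function(x) ifelse(x == "", NA_character_, x)
  mimic_trial_log(data.frame(
    t_next = nexts$t_ms, t_record = recs$t_ms, t_record_end = ends$t_ms,
    stimulus_id = na_if_empty(field(1)), stimulus_kind = field(2),
    eyebrow = na_if_empty(field(3)), emotion = na_if_empty(field(4))))
}

#' Write an N-back event log to CSV
#'
#' Event rows `t_ms,event_type,payload`: one `session` row
#' (`session_index;n_level;score`), `stimulus` rows
#' (`s_audio;s_position`), `input` rows (channel name).
#'
#' @param log an `nback_event_log`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nback_log <- function(log, path) {
  stopifnot(inherits(log, "nback_event_log"))
  ev <- rbind(
    data.frame(t_ms = 0, event_type = "session",
               payload = paste(log$session_index, log$n_level,
                               ifelse(is.na(log$score), "", format(log$score, digits = 17)),
                               sep = ";")),
    data.frame(t_ms = log$stimuli$t_ms, event_type = "stimulus",
               payload = paste(log$stimuli$s_audio, log$stimuli$s_position, sep = ";")),
    if (nrow(log$inputs) > 0)
      data.frame(t_ms = log$inputs$t_ms, event_type = "input",
                 payload = log$inputs$channel))
  ev <- ev[order(ev$t_ms, ev$event_type != "session"), ]
  utils::write.csv(ev, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an N-back event log from CSV
#' @param path file written by [write_nback_log()].
#' @return an `nback_event_log`.
#' @export
read_nback_log <- function(path) {
  ev <- utils::read.csv(path, colClasses = c("numeric", "character", "character"))
  meta <- ev[ev$event_type == "session", ]
  if (nrow(meta) != 1L) stop("expected exactly one session row in ", path)
  mp <- strsplit(meta$payload, ";", fixed = TRUE)[[1]]
  stim <- ev[ev$event_type == "stimulus", ]
  sp <- do.call(rbind, strsplit(stim$payload, ";", fixed = TRUE))
  inp <- ev[ev$event_type == "input", ]
  nback_event_log(
    session_index = as.integer(mp[1]), n_level = as.integer(mp[2]),
    stimuli = data.frame(t_ms = stim$t_ms,
                         s_audio = as.integer(sp[, 1]),
                         s_position = as.integer(sp[, 2])),
    inputs = data.frame(t_ms = inp$t_ms, channel = inp$payload),
    score = if (length(mp) >= 3 && mp[3] != "") as.numeric(mp[3]) else NA_real_)
}
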