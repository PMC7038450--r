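# Dual N-back scoring and stimulus/input condition logic.

#' Score a dual N-back session
#'
#' The session score is the standard N-back performance measure:
#' correct positive inputs divided by (positive stimuli + false-positive
#' inputs), pooled over both channels (audio and position) since the
#' dual task is scored as one task. An input in an inter-stimulus
#' window counts as a correct positive if that channel's stimulus bit
#' is 1, and as a false positive if it is 0. Only window-opening
#' stimuli contribute (the final stimulus opens no response window).
#'
#' @param log an `nback_event_log`.
#' @return list of class `nback_score`: `correct_positive_inputs`,
#'   `positive_stimuli`, `false_positive_inputs`, `score`.
#' @export
score_session <- function(log) {
  stopifnot(inherits(log, "nback_event_log"))
  st <- log$stimuli
  n <- nrow(st)
  cp <- 0L; fp <- 0L; pos <- 0L
  for (i in seq_len(n - 1L)) {
    bits <- window_bits(log, st$t_ms[i], st$t_ms[i + 1L])
    pos <- pos + bits$s_audio + bits$s_position
    cp <- cp + (bits$i_audio & bits$s_audio) + (bits$i_position & bits$s_position)
    fp <- fp + (bits$i_audio & !bits$s_audio) + (bits$i_position & !bits$s_position)
  }
  denom <- pos + fp
  if (denom == 0) stop("score undefined: no positive stimuli and no false-positive inputs")
  structure(list(correct_positive_inputs = as.integer(cp),
                 positive_stimuli = as.integer(pos),
                 false_positive_inputs = as.integer(fp),
                 score = cp / denom),
            class = "nback_score")
}

#' @export
print.nback_score <- function(x, ...) {
  cat(sprintf("N-back score %.4f = %d correct positives / (%d positive stimuli + %d false positives)\n",
              x$score, x$correct_positive_inputs, x$positive_stimuli,
              x$false_positive_inputs))
  invisible(x)
}

#' Stimulus/input condition flags of a window
#'
#' Derives the eight Boolean conditions C1-C8 from the four bits of an
#' inter-stimulus window: stimulus positivity per channel (`s_audio`,
#' `s_position`) and input presence per channel (`i_audio`,
#' `i_position`). The conditions contrast windows in which the
#' participant faces or produces cognitively salient events:
#'
#' * C1 — any positive stimulus: `s_a | s_p`
#' * C2 — any positive input: `i_a | i_p`
#' * C3 — both inputs equal stimuli: `(i_a == s_a) & (i_p == s_p)`
#' * C4 — any positive correct input: `(i_a & s_a) | (i_p & s_p)`
#' * C5 — any positive input or stimulus: `C1 | C2`
#' * C6 — any positive input or stimulus and both inputs match stimuli:
#'   `C5 & C3`
#' * C7 — any input matches stimulus (channel-wise equality on at least
#'   one channel): `(i_a == s_a) | (i_p == s_p)`
#' * C8 — any positive input does not match stimulus (the red feedback
#'   shown by the task program): `(i_a & !s_a) | (i_p & !s_p)`
#'
#' @param s_audio,s_position,i_audio,i_position bits in `{0, 1}`
#'   (vectorized).
#' @return logical matrix with columns `C1..C8` (a vector's worth of
#'   rows), or a named logical vector for scalar input.
#' @export
label_window <- function(s_audio, s_position, i_audio, i_position) {
  stopifnot(all(c(s_audio, s_position, i_audio, i_position) %in% c(0, 1)))
  sa <- as.logical(s_audio); sp <- as.logical(s_position)
  ia <- as.logical(i_audio); ip <- as.logical(i_position)
  c1 <- sa | sp
  c2 <- ia | ip
  c3 <- (ia == sa) & (ip == sp)
  c4 <- (ia & sa) | (ip & sp)
  c5 <- c1 | c2
  c6 <- c5 & c3
  c7 <- (ia == sa) | (ip == sp)
  c8 <- (ia & !sa) | (ip & !sp)
  m <- cbind(C1 = c1, C2 = c2, C3 = c3, C4 = c4,
             C5 = c5, C6 = c6, C7 = c7, C8 = c8)
  if (nrow(m) == 1L) m[1, ] else m
}

#' Truth table of one stimulus/input condition
#'
#' Enumerates the condition over all 16 combinations of the four bits.
#' Rows where the condition holds form the condition set; the
#' complement is the opposite-logic set used as the contrast group in
#' the histogram analysis.
#'
#' @param condition integer 1-8.
#' @return data.frame with 16 rows: `s_audio`, `s_position`, `i_audio`,
#'   `i_position`, `value` (logical).
#' @export
condition_truth_table <- function(condition) {
  stopifnot(length(condition) == 1L, condition %in% 1:8)
  g <- expand.grid(i_position = 0:1, i_audio = 0:1,
                   s_position = 0:1, s_audio = 0:1)
  g <- g[, c("s_audio", "s_position", "i_audio", "i_position")]
  m <- label_window(g$s_audio, g$s_position, g$i_audio, g$i_position)
  g$value <- m[, condition]
  rownames(g) <- NULL
  g
}

#' Session difficulty schedule
#'
#' The nine-session dual N-back schedule: three sessions of dual
#' 2-back, three of dual 3-back, then three of dual 2-back again, so
#' that the middle block re-raises the difficulty once participants get
#' used to 2-back.
#'
#' @return integer vector of length 9: `c(2,2,2,3,3,3,2,2,2)`.
#' @export
difficulty_schedule <- function() {
  c(2L, 2L, 2L, 3L, 3L, 3L, 2L, 2L, 2L)
}
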