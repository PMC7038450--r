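# Synthetic-data generator: forehead pressure streams with expression
# archetypes, plus full simulators for the instructed-mimicking and
# dual N-back experiment protocols.
#
# Spatial activation forms are modeling choices grounded in forehead
# muscle anatomy: raising the eyebrows (frontalis, AU1/AU2) loads the
# upper sensor row broadly; lowering them (corrugator/procerus, AU4)
# loads the medial columns. Per-emotion patterns are fixed cohort-wide
# perturbations of these two archetypes so that pooled classifiers can
# exploit them.

#' Cohort generator configuration
#'
#' All knobs of the synthetic cohort, in ADC counts unless noted.
#'
#' @param noise_sd per-pixel Gaussian sensor noise (ADC counts).
#' @param amplitude peak activation of a fully expressive participant.
#' @param amplitude_floor fraction of `amplitude` retained by the least
#'   expressive participant (expressiveness 0).
#' @param separability scale of the per-emotion perturbation patterns;
#'   larger values make the seven emotions easier to distinguish within
#'   an eyebrow group. The true within-group overlap of real faces is
#'   unknown, so this is an explicit knob, not a claim of realism.
#' @param drift_amplitude amplitude of the slow sinusoidal baseline
#'   drift.
#' @param baseline_range range of per-participant resting headband
#'   pressure levels.
#' @param placement_shift_max maximum absolute per-session column
#'   shift emulating headband re-placement.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(noise_sd = 8, amplitude = 450, amplitude_floor = 0.35,
                          separability = 1, drift_amplitude = 12,
                          baseline_range = c(700, 1500),
                          placement_shift_max = 1L) {
  stopifnot(noise_sd > 0, amplitude > 0,
            amplitude_floor >= 0, amplitude_floor <= 1,
            separability >= 0, drift_amplitude >= 0,
            length(baseline_range) == 2L, baseline_range[1] > 0,
            baseline_range[2] > baseline_range[1],
            placement_shift_max >= 0)
  headroom <- baseline_range[2] + 200 + amplitude * (1 + 0.5 * separability) +
    drift_amplitude + 3 * noise_sd
  if (headroom > ADC_MAX) {
    stop("config exceeds the 12-bit ADC range: baseline + activation + noise = ",
         round(headroom), " > ", ADC_MAX)
  }
  structure(list(noise_sd = noise_sd, amplitude = amplitude,
                 amplitude_floor = amplitude_floor, separability = separability,
                 drift_amplitude = drift_amplitude, baseline_range = baseline_range,
                 placement_shift_max = as.integer(placement_shift_max)),
            class = "cohort_config")
}

EMOTIONS <- c("Neutral", "Joy", "Disgust", "Fear", "Anger", "Sadness", "Surprise")
PORTRAIT_ACTORS <- c("A1", "A2", "A3", "A4")

# Fixed spatial archetypes on the 2x10 grid (canonical pixel order).
# Row 1 is the upper sensor row.
archetype_raise <- function() {
  hump <- 0.6 + 0.4 * exp(-((1:10 - 5.5)^2) / 18)  # broad upper-row load
  c(hump, 0.3 * hump)
}
archetype_lower <- function() {
  medial <- exp(-((1:10 - 5.5)^2) / 4.5)           # medial concentration
  c(0.45 * medial, medial)
}

# Fixed cohort-wide per-emotion perturbation patterns (unit scale).
emotion_perturbations <- function() {
  cols <- 1:10
  outer_cols <- exp(-((cols - 1.5)^2) / 6) + exp(-((cols - 9.5)^2) / 6)
  inner_cols <- exp(-((cols - 5.5)^2) / 2.5)
  left <- exp(-((cols - 3)^2) / 5)
  right <- exp(-((cols - 8)^2) / 5)
  list(
    Neutral = numeric(20),
    Joy = c(0.30 * outer_cols, 0.10 * outer_cols),
    Sadness = c(0.30 * inner_cols, 0.15 * inner_cols),
    Anger = c(0.25 * inner_cols, 0.35 * left),
    Disgust = c(0.15 * left, 0.35 * right),
    Fear = c(0.35 * left, 0.15 * inner_cols),
    Surprise = c(0.35 * right, 0.10 * outer_cols))
}

#' Generate a synthetic participant cohort
#'
#' Every participant gets an individual resting pressure contour, the
#' two eyebrow activation archetypes with individual shape jitter,
#' seven emotion templates derived from the archetypes (Neutral, Joy,
#' Sadness are neutral-brow-like; Anger, Disgust lower-like; Fear,
#' Surprise raise-like), an expressiveness level, and an N-back skill
#' offset. Expressiveness values are the uniform quantiles of `[0, 1]`
#' assigned to participants in random order, so the cohort spans the
#' very expressive to the nearly expressionless and can be ranked for
#' the pool split.
#'
#' @param n_participants cohort size (the emulated studies use 20).
#' @param seed integer seed; the cohort is deterministic given it.
#' @param config a [cohort_config()].
#' @return list of `participant_model` objects.
#' @export
make_cohort <- function(n_participants = 20L, seed = 1L, config = cohort_config()) {
  stopifnot(n_participants >= 1L, inherits(config, "cohort_config"))
  perturb <- emotion_perturbations()
  with_seed(seed, {
    expr_levels <- if (n_participants == 1L) 0.5 else
      sample(seq(0, 1, length.out = n_participants))
    lapply(seq_len(n_participants), function(i) {
      b0 <- stats::runif(1, config$baseline_range[1], config$baseline_range[2])
      phase <- stats::runif(1, 0, 2 * pi)
      contour <- 120 * sin(2 * pi * (1:10) / 10 + phase)
      row_off <- stats::runif(1, -60, 60)
      baseline <- c(b0 + contour + row_off, b0 + 0.8 * contour - row_off) +
        stats::runif(20, -40, 40)
      baseline <- pmax(baseline, 100)
      jitter <- function(v) v * stats::runif(20, 0.9, 1.1)
      t_raise <- jitter(archetype_raise())
      t_lower <- jitter(archetype_lower())
      sep <- config$separability
      emo <- rbind(
        Neutral = perturb$Neutral,
        Joy = 0.9 * sep * perturb$Joy,
        Disgust = t_lower + 0.9 * sep * perturb$Disgust,
        Fear = t_raise + 0.9 * sep * perturb$Fear,
        Anger = t_lower + 0.9 * sep * perturb$Anger,
        Sadness = 0.9 * sep * perturb$Sadness,
        Surprise = t_raise + 0.9 * sep * perturb$Surprise)
      colnames(emo) <- pixel_cols()
      expressiveness <- expr_levels[i]
      structure(list(
        id = sprintf("P%02d", i),
        baseline = stats::setNames(baseline, pixel_cols()),
        template_raise = stats::setNames(t_raise, pixel_cols()),
        template_lower = stats::setNames(t_lower, pixel_cols()),
        emotion_templates = emo,
        expressiveness = expressiveness,
        amplitude = config$amplitude *
          (config$amplitude_floor + (1 - config$amplitude_floor) * expressiveness),
        reaction_amplitude = config$amplitude * (0.7 + 0.3 * expressiveness),
        skill = stats::runif(1, -0.10, 0.10),
        noise_sd = config$noise_sd,
        drift_amplitude = config$drift_amplitude,
        placement_shift_max = config$placement_shift_max,
        seed = sample.int(2^30, 1)),
        class = "participant_model")
    })
  })
}

#' @export
print.participant_model <- function(x, ...) {
  cat(sprintf("<participant_model> %s, expressiveness %.2f, amplitude %.0f, noise sd %.1f\n",
              x$id, x$expressiveness, x$amplitude, x$noise_sd))
  invisible(x)
}

# Shift the 10 columns of each sensor row by `shift` positions (may be
# fractional; linear interpolation, edge replication). Emulates
# headband re-placement along the forehead; re-seating is usually a
# fraction of the 1.5 cm sensor pitch.
shift_columns <- function(v20, shift) {
  if (shift == 0) return(v20)
  sh <- function(v) {
    pos <- pmin(pmax(seq_along(v) - shift, 1), length(v))
    lo <- floor(pos)
    hi <- ceiling(pos)
    v[lo] + (pos - lo) * (v[hi] - v[lo])
  }
  c(sh(v20[1:10]), sh(v20[11:20]))
}

# Per-session placement shift in columns: continuous, mostly sub-pitch.
draw_placement_shift <- function(p) {
  if (p$placement_shift_max <= 0) return(0)
  min(max(stats::rnorm(1, 0, 0.35), -p$placement_shift_max), p$placement_shift_max)
}

# Trapezoidal activation envelope on frame times (ms).
envelope <- function(t, on, ramp_up, hold_end, ramp_down) {
  pmin(1, pmax(0, (t - (on - ramp_up)) / ramp_up)) *
    pmin(1, pmax(0, ((hold_end + ramp_down) - t) / ramp_down))
}

# Shared raw-frame assembly: baseline + drift + bursts + noise,
# quantized to 12-bit integers. `bursts` is a list of
# list(pattern = 20-vector, on, ramp_up, hold_end, ramp_down).
build_stream <- function(p, duration_ms, shift, bursts) {
  t <- seq(0, duration_ms, by = 15)
  n <- length(t)
  base <- shift_columns(p$baseline, shift)
  drift_phase <- stats::runif(1, 0, 2 * pi)
  drift <- p$drift_amplitude * sin(2 * pi * t / 90000 + drift_phase)
  values <- matrix(rep(base, each = n), nrow = n) + drift
  for (b in bursts) {
    lo <- max(1L, floor((b$on - b$ramp_up) / 15) + 1L)
    hi <- min(n, ceiling((b$hold_end + b$ramp_down) / 15) + 1L)
    if (lo > hi) next
    e <- envelope(t[lo:hi], b$on, b$ramp_up, b$hold_end, b$ramp_down)
    values[lo:hi, ] <- values[lo:hi, ] +
      e %o% shift_columns(b$pattern, shift)
  }
  values <- values + matrix(stats::rnorm(n * 20L, 0, p$noise_sd), nrow = n)
  values <- pmin(pmax(round(values), 0), ADC_MAX)
  frame_stream(t, values)
}

# Stimulus schedule of one mimicking session: 5 repetitions of the
# 60-stimulus sequence (32 basic figures + 28 portraits) = 300 trials.
mimic_stimulus_schedule <- function() {
  group1 <- data.frame(stimulus_id = paste0("g1_", c("N", "L", "R")),
                       eyebrow = c("Neutral", "Lower", "Raise"))
  group2 <- data.frame(stimulus_id = paste0("g2_", c("N1", "L1", "L2", "R1", "R2")),
                       eyebrow = c("Neutral", "Lower", "Lower", "Raise", "Raise"))
  out <- list()
  for (s in 1:5) {
    for (g in list(group1, group2)) {
      for (rep_i in 1:4) {
        gg <- g[sample(nrow(g)), , drop = FALSE]
        gg$emotion <- NA_character_
        gg$stimulus_kind <- "basic"
        out[[length(out) + 1L]] <- gg
      }
    }
    for (actor in PORTRAIT_ACTORS) {
      emos <- sample(EMOTIONS)
      out[[length(out) + 1L]] <- data.frame(
        stimulus_id = paste0(actor, "_", emos),
        eyebrow = NA_character_, emotion = emos, stimulus_kind = "portrait")
    }
  }
  do.call(rbind, out)
}

#' Simulate one instructed-mimicking session
#'
#' Emulates the full stimulus protocol: 5 repetitions of a 60-stimulus
#' sequence — 32 basic eyebrow figures (two groups, four
#' within-repetition shuffles each: group 1 has one figure per eyebrow
#' state, group 2 has five cartoon faces composed of 1 neutral, 2
#' lowered, 2 raised) and 28 emotional portraits (4 actors x 7
#' emotions, emotions shuffled per actor) — for 300 trials total. Per
#' trial the participant's activation template is added to the
#' baseline under a trapezoidal envelope (ramp about 0.4 s before the
#' 'record' click, held through the two-second countdown, released
#' after), then sensor noise, slow drift and integer quantization are
#' applied.
#'
#' @param p a `participant_model`.
#' @param seed integer seed; defaults to the participant's own.
#' @return list with `stream` (a `frame_stream`) and `log` (a
#'   `mimic_trial_log` with 300 trials).
#' @export
simulate_mimic_session <- function(p, seed = p$seed) {
  stopifnot(inherits(p, "participant_model"))
  with_seed(seed, {
    sched <- mimic_stimulus_schedule()
    ntr <- nrow(sched)
    t_next <- numeric(ntr); t_record <- numeric(ntr)
    cursor <- 2000
    for (i in seq_len(ntr)) {
      t_next[i] <- cursor
      t_record[i] <- t_next[i] + round(stats::runif(1, 1200, 2600))
      cursor <- t_record[i] + 2000 + 1000 + round(stats::runif(1, 200, 600))
    }
    t_record_end <- t_record + 2000
    log <- mimic_trial_log(data.frame(
      t_next = t_next, t_record = t_record, t_record_end = t_record_end,
      stimulus_id = sched$stimulus_id, eyebrow = sched$eyebrow,
      emotion = sched$emotion, stimulus_kind = sched$stimulus_kind))
    shift <- draw_placement_shift(p)
    bursts <- lapply(seq_len(ntr), function(i) {
      pattern <- if (sched$stimulus_kind[i] == "basic") {
        switch(sched$eyebrow[i],
               Neutral = numeric(20),
               Lower = p$template_lower,
               Raise = p$template_raise)
      } else {
        p$emotion_templates[sched$emotion[i], ]
      }
      list(pattern = p$amplitude * stats::runif(1, 0.85, 1.15) * pattern,
           on = t_record[i], ramp_up = 400,
           hold_end = t_record_end[i] + 300, ramp_down = 500)
    })
    stream <- build_stream(p, cursor + 1500, shift, bursts)
    list(stream = stream, log = log)
  })
}

#' Behavioural model for the N-back task
#'
#' Response probabilities of a simulated participant: hit probability
#' per N-level (3-back is harder than 2-back), false-positive keypress
#' probability per negative stimulus and channel, and the probability
#' of a visible facial reaction in windows with red feedback (wrong
#' positive input), missed positives, or positive events. Reaction
#' probabilities are further scaled by the participant's
#' expressiveness at simulation time.
#'
#' @param hit_prob named vector of hit probabilities, names `"2"` and
#'   `"3"`.
#' @param false_positive_prob probability of a spurious positive input
#'   on a negative stimulus.
#' @param react_red,react_miss,react_pos reaction probabilities for
#'   red-feedback, missed-positive and positive-event windows.
#' @return list of class `behavior_model`.
#' @export
behavior_model <- function(hit_prob = c("2" = 0.50, "3" = 0.20),
                           false_positive_prob = 0.08,
                           react_red = 0.9, react_miss = 0.8, react_pos = 0.1) {
  probs <- c(hit_prob, false_positive_prob, react_red, react_miss, react_pos)
  stopifnot(all(probs >= 0 & probs <= 1), all(c("2", "3") %in% names(hit_prob)))
  structure(list(hit_prob = hit_prob, false_positive_prob = false_positive_prob,
                 react_red = react_red, react_miss = react_miss,
                 react_pos = react_pos),
            class = "behavior_model")
}

# N-back stimulus sequence with inflated match probability (the task
# program schedules deliberate matches; plain uniform draws would give
# too few positives).
nback_sequence <- function(n_stim, n_level, n_symbols, match_prob = 0.25) {
  v <- integer(n_stim)
  for (i in seq_len(n_stim)) {
    v[i] <- if (i > n_level && stats::runif(1) < match_prob) {
      v[i - n_level]
    } else {
      sample.int(n_symbols, 1)
    }
  }
  bits <- integer(n_stim)
  idx <- (n_level + 1):n_stim
  bits[idx] <- as.integer(v[idx] == v[idx - n_level])
  list(values = v, bits = bits)
}

#' Simulate one dual N-back session
#'
#' Generates 21-24 stimulus pairs at 3 s spacing with ground-truth
#' positivity bits from an N-back match process on each channel, draws
#' the participant's keypresses from the behavioural model (hit
#' probability shifted by the participant's skill), and injects facial
#' reactions — eyebrow-template activations of about a second — into
#' red-feedback, missed-positive and positive-event windows with
#' probability scaled by expressiveness. A tonic corrugator-like
#' tension proportional to the session's experienced error rate (and
#' to expressiveness) models the sustained brow loading seen under
#' mental effort. Occasional broadband head-motion-like disturbances
#' are added independently. The headband is virtually re-seated every
#' session (random column shift).
#'
#' @param p a `participant_model`.
#' @param b a [behavior_model()].
#' @param n_level 2 or 3.
#' @param seed integer seed.
#' @param session_index session position 1-9.
#' @return list with `stream` (a `frame_stream`) and `log` (an
#'   `nback_event_log` with its `score` filled in).
#' @export
simulate_nback_session <- function(p, b = behavior_model(), n_level = 2L,
                                   seed = p$seed, session_index = 1L) {
  stopifnot(inherits(p, "participant_model"), inherits(b, "behavior_model"))
  with_seed(seed, {
    n_stim <- sample(21:24, 1)
    t_stim <- 1000 + (seq_len(n_stim) - 1) * 3000
    audio <- nback_sequence(n_stim, n_level, n_symbols = 8L)
    position <- nback_sequence(n_stim, n_level, n_symbols = 9L)
    hit <- min(1, max(0, b$hit_prob[[as.character(n_level)]] + p$skill))
    inputs <- list()
    for (i in seq_len(n_stim)) {
      for (ch in c("audio", "position")) {
        bit <- if (ch == "audio") audio$bits[i] else position$bits[i]
        pr <- if (bit == 1) hit else b$false_positive_prob
        if (stats::runif(1) < pr) {
          inputs[[length(inputs) + 1L]] <- data.frame(
            t_ms = t_stim[i] + round(stats::runif(1, 600, 2400)), channel = ch)
        }
      }
    }
    inputs <- if (length(inputs)) do.call(rbind, inputs) else
      data.frame(t_ms = numeric(), channel = character())
    inputs <- inputs[order(inputs$t_ms), , drop = FALSE]
    log <- nback_event_log(session_index, n_level,
                           data.frame(t_ms = t_stim, s_audio = audio$bits,
                                      s_position = position$bits),
                           inputs)
    # facial reactions per inter-stimulus window; whether a reaction is
    # visible at all is the expressiveness phenotype (the least
    # expressive participants keep the same face the whole session)
    react_scale <- p$expressiveness^2
    bursts <- list()
    for (i in seq_len(n_stim - 1L)) {
      bits <- window_bits(log, t_stim[i], t_stim[i + 1L])
      red <- (bits$i_audio & !bits$s_audio) | (bits$i_position & !bits$s_position)
      miss <- (bits$s_audio & !bits$i_audio) | (bits$s_position & !bits$i_position)
      pos <- bits$s_audio | bits$s_position | bits$i_audio | bits$i_position
      base_pr <- if (red) b$react_red else if (miss) b$react_miss else
        if (pos) b$react_pos else 0.02
      if (stats::runif(1) < base_pr * react_scale) {
        w <- stats::runif(1)
        pattern <- w * p$template_lower + (1 - w) * p$template_raise
        # spontaneous reactions are usually asymmetric: emphasize one
        # side of the forehead, which moves the intensity centroid and
        # the second-order moments of the difference key frames
        side <- sample(c(-1, 1), 1)
        lateral <- exp(-((1:10 - (5.5 + side * 2.5))^2) / 8)
        pattern <- pattern * c(lateral, lateral)
        on <- t_stim[i] + stats::runif(1, 200, 800)
        # spontaneous (not instructed) reactions scale with
        # expressiveness itself: the least expressive participants show
        # essentially no visible reaction during the task
        bursts[[length(bursts) + 1L]] <- list(
          pattern = p$reaction_amplitude * stats::runif(1, 0.5, 1.2) * pattern,
          on = on, ramp_up = 200,
          hold_end = on + stats::runif(1, 1000, 2200), ramp_down = 300)
      }
      if (stats::runif(1) < 0.08) { # head motion: broad pressure shift
        on <- t_stim[i] + stats::runif(1, 200, 2000)
        bursts[[length(bursts) + 1L]] <- list(
          pattern = rep(stats::runif(1, 30, 120), 20) * stats::runif(20, 0.7, 1.3),
          on = on, ramp_up = 150,
          hold_end = on + stats::runif(1, 150, 450), ramp_down = 150)
      }
    }
    # Tonic mental-effort tension: sustained corrugator-like load over
    # the whole session, proportional to the error rate the participant
    # experiences (misses + wrong positives) and to expressiveness.
    errors <- 0L
    for (i in seq_len(n_stim - 1L)) {
      bits <- window_bits(log, t_stim[i], t_stim[i + 1L])
      errors <- errors +
        ((bits$i_audio & !bits$s_audio) | (bits$i_position & !bits$s_position)) +
        ((bits$s_audio & !bits$i_audio) | (bits$s_position & !bits$i_position))
    }
    error_rate <- errors / (n_stim - 1L)
    tonic <- 2 * error_rate * p$expressiveness^2
    if (tonic > 0) {
      bursts[[length(bursts) + 1L]] <- list(
        pattern = p$reaction_amplitude * tonic * p$template_lower,
        on = 2000, ramp_up = 2000,
        hold_end = t_stim[n_stim] + 1000, ramp_down = 2000)
    }
    shift <- draw_placement_shift(p)
    stream <- build_stream(p, t_stim[n_stim] + 3000, shift, bursts)
    log$score <- score_session(log)$score
    list(stream = stream, log = log)
  })
}

#' Simulate the nine-session N-back study of one participant
#'
#' Runs [simulate_nback_session()] once per entry of
#' [difficulty_schedule()] (2,2,2,3,3,3,2,2,2).
#'
#' @param p a `participant_model`.
#' @param b a [behavior_model()].
#' @param seed integer seed.
#' @return list of 9 session lists (`stream`, `log`).
#' @export
simulate_nback_study <- function(p, b = behavior_model(), seed = p$seed) {
  sched <- difficulty_schedule()
  lapply(seq_along(sched), function(si) {
    simulate_nback_session(p, b, n_level = sched[si],
                           seed = (seed + 7919L * si) %% 2^30,
                           session_index = si)
  })
}
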