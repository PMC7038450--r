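# Expected truth table of the eight stimulus/input conditions, derived
# by hand from their definitions; rows in binary order of
# (s_audio, s_position, i_audio, i_position).
EXPECTED_CONDITIONS <- matrix(as.logical(c(
  # C1 C2 C3 C4 C5 C6 C7 C8
  0, 0, 1, 0, 0, 0, 1, 0,  # 0000
  0, 1, 0, 0, 1, 0, 1, 1,  # 0001
  0, 1, 0, 0, 1, 0, 1, 1,  # 0010
  0, 1, 0, 0, 1, 0, 0, 1,  # 0011
  1, 0, 0, 0, 1, 0, 1, 0,  # 0100
  1, 1, 1, 1, 1, 1, 1, 0,  # 0101
  1, 1, 0, 0, 1, 0, 0, 1,  # 0110
  1, 1, 0, 1, 1, 0, 1, 1,  # 0111
  1, 0, 0, 0, 1, 0, 1, 0,  # 1000
  1, 1, 0, 0, 1, 0, 0, 1,  # 1001
  1, 1, 1, 1, 1, 1, 1, 0,  # 1010
  1, 1, 0, 1, 1, 0, 1, 1,  # 1011
  1, 0, 0, 0, 1, 0, 0, 0,  # 1100
  1, 1, 0, 1, 1, 0, 1, 0,  # 1101
  1, 1, 0, 1, 1, 0, 1, 0,  # 1110
  1, 1, 1, 1, 1, 1, 1, 0   # 1111
)), ncol = 8, byrow = TRUE, dimnames = list(NULL, paste0("C", 1:8)))

bit_rows <- expand.grid(i_position = 0:1, i_audio = 0:1,
                        s_position = 0:1, s_audio = 0:1)[,
                        c("s_audio", "s_position", "i_audio", "i_position")]

test_that("condition logic matches the hand-derived truth tables", {
  got <- label_window(bit_rows$s_audio, bit_rows$s_position,
                      bit_rows$i_audio, bit_rows$i_position)
  expect_equal(unname(got), unname(EXPECTED_CONDITIONS))
  # spot checks from the documented condition semantics
  expect_equal(unname(label_window(0, 0, 0, 0)),
               c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(unname(label_window(1, 0, 1, 0)),
               c(rep(TRUE, 7), FALSE))
  w <- label_window(0, 0, 1, 0)  # wrong positive input: red feedback
  expect_true(w[["C2"]] && w[["C8"]])
  expect_false(w[["C3"]] || w[["C4"]])
})

test_that("truth-table enumeration, complements and implications hold", {
  for (ci in 1:8) {
    tt <- condition_truth_table(ci)
    expect_equal(nrow(tt), 16)
    expect_equal(tt$value, unname(EXPECTED_CONDITIONS[, ci]))
    # condition set and opposite-logic set partition the 16 rows
    expect_equal(sum(tt$value) + sum(!tt$value), 16)
  }
  expect_equal(sum(condition_truth_table(1)$value), 12)
  expect_false(any(EXPECTED_CONDITIONS[, "C3"] & EXPECTED_CONDITIONS[, "C8"]))
  expect_true(all(EXPECTED_CONDITIONS[, "C6"] <= EXPECTED_CONDITIONS[, "C3"]))
  expect_true(all(EXPECTED_CONDITIONS[, "C6"] <= EXPECTED_CONDITIONS[, "C5"]))
  expect_true(all(EXPECTED_CONDITIONS[, "C4"] <= EXPECTED_CONDITIONS[, "C2"]))
  expect_true(all(EXPECTED_CONDITIONS[, "C8"] <= EXPECTED_CONDITIONS[, "C2"]))
})

score_log <- function(s_audio, inputs_t, inputs_ch) {
  n <- length(s_audio)
  nback_event_log(1, 2,
                  data.frame(t_ms = (0:(n - 1)) * 3000, s_audio = s_audio,
                             s_position = 0),
                  inputs = data.frame(t_ms = inputs_t, channel = inputs_ch))
}

test_that("session scores follow the correct-positive ratio", {
  # 10 positive window-opening stimuli, all answered, no false positives
  s <- c(rep(1, 10), rep(0, 5), 0)
  log <- score_log(s, (0:9) * 3000 + 1000, rep("audio", 10))
  r <- score_session(log)
  expect_equal(r$score, 1.0)
  expect_equal(r$positive_stimuli, 10L)
  # 6 answered, 2 false positives -> 6 / 12
  log2 <- score_log(s, c((0:5) * 3000 + 1000, c(10, 11) * 3000 + 1000),
                    rep("audio", 8))
  r2 <- score_session(log2)
  expect_equal(r2$score, 0.5)
  expect_equal(r2$false_positive_inputs, 2L)
  # no positives and no inputs: undefined
  expect_error(score_session(score_log(rep(0, 5), numeric(), character())),
               "undefined")
})

test_that("monotonicity: false positives never raise the score", {
  s <- c(rep(1, 6), rep(0, 6))
  base <- score_session(score_log(s, (0:3) * 3000 + 1000, rep("audio", 4)))
  worse <- score_session(score_log(s, c((0:3) * 3000 + 1000, 7 * 3000 + 1000),
                                   rep("audio", 5)))
  better <- score_session(score_log(s, (0:4) * 3000 + 1000, rep("audio", 5)))
  expect_lt(worse$score, base$score)
  expect_gt(better$score, base$score)
  expect_true(base$score >= 0 && base$score <= 1)
})

test_that("simulated responders score near the closed-form expectation", {
  hit <- 0.7; fp <- 0.05
  n <- 201  # 200 window-opening stimuli
  withr::with_seed(101, {
    s_audio <- rbinom(n, 1, 0.25)
    s_pos <- rbinom(n, 1, 0.25)
    inp <- list()
    for (i in seq_len(n)) {
      for (ch in c("audio", "position")) {
        bit <- if (ch == "audio") s_audio[i] else s_pos[i]
        if (runif(1) < (if (bit == 1) hit else fp)) {
          inp[[length(inp) + 1L]] <- data.frame(
            t_ms = (i - 1) * 3000 + 1000, channel = ch)
        }
      }
    }
    log <- nback_event_log(1, 2,
                           data.frame(t_ms = (0:(n - 1)) * 3000,
                                      s_audio = s_audio, s_position = s_pos),
                           inputs = do.call(rbind, inp))
    r <- score_session(log)
    pos <- sum(s_audio[-n]) + sum(s_pos[-n])
    neg <- 2 * (n - 1) - pos
    expected <- hit * pos / (pos + fp * neg)
    expect_lt(abs(r$score - expected), 0.05)
  })
})

test_that("the difficulty schedule is the 2/3/2 block design", {
  sched <- difficulty_schedule()
  expect_length(sched, 9)
  expect_equal(sched[4:6], rep(3L, 3))
  expect_equal(sched[c(1, 9)], c(2L, 2L))
})
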