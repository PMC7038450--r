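# End-to-end cohort drivers tying the generator to the feature and
# statistics pipeline. These are what the command-line entry points
# and the worked examples run.

#' Run the mimicking experiment for a whole cohort
#'
#' Simulates one mimicking session per participant, segments each
#' stream by its trial log, and extracts the 80 window features,
#' returning one pooled feature table (the basis of the three
#' classification modes).
#'
#' @param cohort list of `participant_model`s from [make_cohort()].
#' @param seed integer seed; per-participant seeds are derived from it.
#' @return feature table (see [mimic_feature_table()]) with
#'   `300 * length(cohort)` rows.
#' @export
run_mimic_experiment <- function(cohort, seed = 1L) {
  tables <- lapply(seq_along(cohort), function(i) {
    sim <- simulate_mimic_session(cohort[[i]], seed = (seed + 104729L * i) %% 2^30)
    windows <- segment_mimic(sim$stream, sim$log)
    mimic_feature_table(windows, participant = cohort[[i]]$id)
  })
  do.call(rbind, tables)
}

#' Run the N-back experiment for a whole cohort
#'
#' Simulates the nine-session study per participant, segments every
#' session into inter-stimulus windows, extracts the 80 features and
#' the C1-C8 condition flags per window, and scores every session.
#'
#' @param cohort list of `participant_model`s.
#' @param behavior a [behavior_model()].
#' @param seed integer seed.
#' @return list with `windows` (data.frame: `participant`,
#'   `session_index`, `n_level`, `score`, `C1..C8`, `f1..f80`) and
#'   `sessions` (data.frame: `participant`, `session_index`,
#'   `n_level`, `score`).
#' @export
run_nback_experiment <- function(cohort, behavior = behavior_model(), seed = 1L) {
  win_rows <- list()
  ses_rows <- list()
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    study <- simulate_nback_study(p, behavior, seed = (seed + 15485863L * i) %% 2^30)
    for (session in study) {
      windows <- segment_interstimulus(session$stream, session$log)
      feats <- t(vapply(windows, window_features, numeric(80)))
      colnames(feats) <- paste0("f", seq_len(80))
      conds <- t(vapply(windows, function(w) w$label$conditions, logical(8)))
      win_rows[[length(win_rows) + 1L]] <- data.frame(
        participant = p$id,
        session_index = session$log$session_index,
        n_level = session$log$n_level,
        score = session$log$score,
        conds, feats)
      ses_rows[[length(ses_rows) + 1L]] <- data.frame(
        participant = p$id,
        session_index = session$log$session_index,
        n_level = session$log$n_level,
        score = session$log$score)
    }
  }
  list(windows = do.call(rbind, win_rows), sessions = do.call(rbind, ses_rows))
}

#' Condition scan on an N-back cohort run
#'
#' Z-scores the window features of [run_nback_experiment()] output and
#' runs the per-condition balanced chi-square scan.
#'
#' @param nback_run output of [run_nback_experiment()].
#' @param alpha significance level.
#' @return the [condition_scan()] summary (8 rows).
#' @export
nback_condition_summary <- function(nback_run, alpha = 0.05) {
  w <- nback_run$windows
  Z <- zscore_features(as.matrix(w[, paste0("f", 1:80)]))
  condition_scan(Z, as.matrix(w[, paste0("C", 1:8)]), alpha = alpha)
}

#' Session-level median-split evaluation of an N-back cohort run
#'
#' Aggregates each session's z-scored window features into 320 session
#' features and evaluates the median-score split for the three
#' participant pools.
#'
#' @param nback_run output of [run_nback_experiment()].
#' @param cohort the cohort the run came from (supplies the
#'   expressiveness ranking).
#' @param spec,k,seed passed to [median_split_eval()].
#' @return a `median_split_eval` result.
#' @export
nback_session_eval <- function(nback_run, cohort,
                               spec = classifier_spec("subspace_knn"),
                               k = 5L, seed = 1L) {
  w <- nback_run$windows
  Z <- zscore_features(as.matrix(w[, paste0("f", 1:80)]))
  key <- paste(w$participant, w$session_index)
  keys <- unique(key)
  ses <- t(vapply(keys, function(kk) session_features(Z[key == kk, , drop = FALSE]),
                  numeric(320)))
  first <- match(keys, key)
  expressiveness <- stats::setNames(
    vapply(cohort, function(p) p$expressiveness, 0),
    vapply(cohort, function(p) p$id, ""))
  median_split_eval(ses, scores = w$score[first],
                    participant = w$participant[first],
                    expressiveness = expressiveness,
                    spec = spec, k = k, seed = seed)
}
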