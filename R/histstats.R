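# Condition-conditioned histogram pairs, balancing, two-histogram
# chi-square statistics, per-condition significance scans, and
# session-level aggregation.

HIST_RANGE <- c(-2, 2)
HIST_BINS <- 26L
CHISQ_DF <- 25L

hist_edges <- function() seq(HIST_RANGE[1], HIST_RANGE[2], length.out = HIST_BINS + 1L)

# Bin z-scored values into the 26 equal bins over [-2, 2]; values
# outside the range are clipped into the boundary bins so every window
# contributes.
bin_values <- function(values) {
  width <- diff(HIST_RANGE) / HIST_BINS
  idx <- floor((values - HIST_RANGE[1]) / width) + 1L
  pmin(pmax(idx, 1L), HIST_BINS)
}

#' Histogram pair for a condition split
#'
#' Splits z-scored feature values into the condition group and its
#' opposite-logic group and bins each into a 26-bin histogram over
#' `[-2, 2]` (out-of-range values are clipped into the edge bins).
#'
#' @param values numeric vector of z-scored per-window feature values.
#' @param mask logical vector, `TRUE` = window under the condition.
#' @param condition optional condition name for error messages.
#' @return object of class `hist_pair`: `edges` (27 boundaries),
#'   `counts_a` (condition group), `counts_b` (opposite group),
#'   `balanced` flag.
#' @export
paired_histograms <- function(values, mask, condition = "condition") {
  stopifnot(length(values) == length(mask))
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty group under ", condition)
  if (all(mask)) stop("empty group under the opposite of ", condition)
  bins <- bin_values(values)
  counts_a <- tabulate(bins[mask], nbins = HIST_BINS)
  counts_b <- tabulate(bins[!mask], nbins = HIST_BINS)
  structure(list(edges = hist_edges(), counts_a = as.numeric(counts_a),
                 counts_b = as.numeric(counts_b), balanced = FALSE),
            class = "hist_pair")
}

#' Balance a histogram pair
#'
#' Rescales each histogram so the two have equal mass: every bin is
#' divided by its histogram's sum and multiplied by half the total
#' window count, so together the pair sums to `total_windows`.
#' Balancing preserves each histogram's shape.
#'
#' @param pair a `hist_pair`.
#' @param total_windows total number of windows in the experiment.
#' @return the balanced `hist_pair`.
#' @export
balance_pair <- function(pair, total_windows) {
  stopifnot(inherits(pair, "hist_pair"))
  sa <- sum(pair$counts_a); sb <- sum(pair$counts_b)
  if (sa <= 0 || sb <= 0) stop("cannot balance a zero-sum histogram")
  half <- total_windows / 2
  pair$counts_a <- pair$counts_a / sa * half
  pair$counts_b <- pair$counts_b / sb * half
  pair$balanced <- TRUE
  pair
}

#' Two-histogram chi-square consistency statistic
#'
#' The chi-square critical value between a balanced histogram pair:
#' `CV = sum_i (a_i - b_i)^2 / (a_i + b_i)` over bins with positive
#' total, testing the null hypothesis that both histograms are sampled
#' from one distribution. The degrees of freedom are fixed at 25
#' (bins - 1) regardless of skipped empty bins, and the p-value is the
#' upper tail of the chi-square distribution at the CV. A larger CV
#' means the two distributions are more distinct.
#'
#' @param pair a balanced `hist_pair` (see [balance_pair()]); an
#'   unbalanced pair with equal sums is accepted.
#' @param feature_index optional feature index echoed in the result.
#' @return object of class `chisq_pair`: `cv`, `df`, `p`,
#'   `feature_index`.
#' @export
chi_square_pair <- function(pair, feature_index = NA_integer_) {
  stopifnot(inherits(pair, "hist_pair"))
  sa <- sum(pair$counts_a); sb <- sum(pair$counts_b)
  if (!pair$balanced && abs(sa - sb) > 1e-9 * max(sa, sb, 1)) {
    stop("histogram pair is not balanced (sums ", sa, " and ", sb, ")")
  }
  a <- pair$counts_a; b <- pair$counts_b
  keep <- (a + b) > 0
  cv <- sum((a[keep] - b[keep])^2 / (a[keep] + b[keep]))
  structure(list(cv = cv, df = CHISQ_DF,
                 p = stats::pchisq(cv, df = CHISQ_DF, lower.tail = FALSE),
                 feature_index = feature_index),
            class = "chisq_pair")
}

#' Per-condition chi-square scan over all features
#'
#' For each stimulus/input condition and each of the 80 features,
#' builds the condition/opposite histogram pair, balances it to the
#' total window count, and computes the two-histogram chi-square CV.
#' Per condition it reports the feature attaining the maximum CV (the
#' most significant feature), its p-value, and how many features fall
#' below the 0.05 significance level. No multiple-testing correction
#' is applied.
#'
#' @param features numeric matrix (windows x features) of z-scored
#'   feature values, or a feature table (its `f*` columns are used).
#' @param conditions logical matrix (windows x conditions), e.g. the
#'   `C1..C8` flags stacked from [segment_interstimulus()] windows.
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per condition: `condition`,
#'   `best_feature`, `cv`, `p`, `n_significant`, `skipped`; the full
#'   CV and p matrices are attached as attributes `cv_matrix` and
#'   `p_matrix`.
#' @export
condition_scan <- function(features, conditions, alpha = 0.05) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  conditions <- as.matrix(conditions)
  stopifnot(nrow(X) == nrow(conditions))
  total <- nrow(X)
  cond_names <- colnames(conditions) %||% paste0("C", seq_len(ncol(conditions)))
  nf <- ncol(X)
  cv_mat <- matrix(NA_real_, ncol(conditions), nf,
                   dimnames = list(cond_names, colnames(X)))
  p_mat <- cv_mat
  out <- data.frame(condition = cond_names, best_feature = NA_integer_,
                    cv = NA_real_, p = NA_real_, n_significant = NA_integer_,
                    skipped = FALSE)
  for (ci in seq_len(ncol(conditions))) {
    mask <- as.logical(conditions[, ci])
    if (!any(mask) || all(mask)) {
      out$skipped[ci] <- TRUE
      next
    }
    for (fi in seq_len(nf)) {
      pair <- balance_pair(paired_histograms(X[, fi], mask, cond_names[ci]), total)
      cs <- chi_square_pair(pair, feature_index = fi)
      cv_mat[ci, fi] <- cs$cv
      p_mat[ci, fi] <- cs$p
    }
    best <- which.max(cv_mat[ci, ])
    out$best_feature[ci] <- best
    out$cv[ci] <- cv_mat[ci, best]
    out$p[ci] <- p_mat[ci, best]
    out$n_significant[ci] <- sum(p_mat[ci, ] < alpha)
  }
  attr(out, "cv_matrix") <- cv_mat
  attr(out, "p_matrix") <- p_mat
  out
}

#' Session-level aggregate features
#'
#' Aggregates the per-window feature vectors of one session into 320
#' session features: for each of the 80 features, its mean, standard
#' deviation, range, and excess kurtosis over the session's windows
#' (zero-variance features have range 0 and kurtosis defined as 0).
#' Ordering is feature-major: `f1_mean, f1_sd, f1_range, f1_kurtosis,
#' f2_mean, ...`.
#'
#' @param windows numeric matrix (windows x 80) of the session's
#'   feature vectors.
#' @return named numeric vector of length 320.
#' @export
session_features <- function(windows) {
  X <- as.matrix(windows)
  if (nrow(X) < 4L) stop("session too short: need at least 4 windows")
  base <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  out <- numeric(4L * ncol(X))
  nm <- character(length(out))
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    k <- (j - 1L) * 4L
    out[k + 1:4] <- c(mean(v), stats::sd(v), max(v) - min(v), excess_kurtosis(v))
    nm[k + 1:4] <- paste0(base[j], "_", c("mean", "sd", "range", "kurtosis"))
  }
  stats::setNames(out, nm)
}

#' Median-split session classification
#'
#' Labels every session as above or below the median N-back score
#' (computed over all sessions) and cross-validates a subspace-KNN
#' classifier on the session-level aggregate features, separately for
#' three participant pools: everyone, the least expressive half, and
#' the most expressive half.
#'
#' @param sessions numeric matrix (sessions x 320) from
#'   [session_features()].
#' @param scores per-session N-back scores.
#' @param participant per-session participant identifiers.
#' @param expressiveness named vector of per-participant
#'   expressiveness used to rank the pools (names = participant ids).
#' @param spec classifier; default subspace-KNN.
#' @param k folds.
#' @param seed integer seed.
#' @return list of class `median_split_eval` with `eval_report`s
#'   `all`, `least_expressive`, `most_expressive`, plus the `median`
#'   score and the pool memberships.
#' @export
median_split_eval <- function(sessions, scores, participant, expressiveness,
                              spec = classifier_spec("subspace_knn"),
                              k = 5L, seed = 1L) {
  X <- as.matrix(sessions)
  stopifnot(nrow(X) == length(scores), length(scores) == length(participant))
  med <- stats::median(scores)
  label <- factor(ifelse(scores > med, "above", "below"),
                  levels = c("below", "above"))
  if (nlevels(droplevels(label)) < 2L) stop("degenerate split: all sessions on one side of the median")
  ids <- names(expressiveness)
  ord <- ids[order(expressiveness)]
  n_half <- floor(length(ord) / 2)
  least <- ord[seq_len(n_half)]
  most <- ord[seq(length(ord) - n_half + 1L, length(ord))]
  run_pool <- function(keep, pool_seed) {
    df <- data.frame(X[keep, , drop = FALSE], check.names = FALSE)
    names(df) <- paste0("f", seq_len(ncol(df)))
    df$label <- droplevels(label[keep])
    crossval(df, spec = spec, k = k, seed = pool_seed)
  }
  structure(list(
    all = run_pool(rep(TRUE, nrow(X)), seed),
    least_expressive = run_pool(participant %in% least, seed + 1L),
    most_expressive = run_pool(participant %in% most, seed + 2L),
    median = med, least = least, most = most),
    class = "median_split_eval")
}

#' @export
print.median_split_eval <- function(x, ...) {
  cat(sprintf("median score %.4f | accuracy: all %.3f, least expressive %.3f, most expressive %.3f\n",
              x$median, x$all$accuracy, x$least_expressive$accuracy,
              x$most_expressive$accuracy))
  invisible(x)
}
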