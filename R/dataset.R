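# Feature-table assembly, normalization, classification modes,
# cross-validation, and cross-mode transfer for the mimicking
# experiment.

FEATURE_COL_RE <- "^f[0-9]+$"

feature_cols <- function(table) grep(FEATURE_COL_RE, names(table), value = TRUE)

feature_matrix <- function(table) as.matrix(table[, feature_cols(table), drop = FALSE])

#' Build a feature table from mimicking windows
#'
#' Runs the key-frame + image-moment pipeline on every window and
#' stacks the 80-feature vectors into a rectangular table with the
#' window labels alongside.
#'
#' @param windows list of `tpm_window` objects from [segment_mimic()].
#' @param participant participant identifier attached to every row.
#' @return data.frame with columns `participant`, `stimulus_id`,
#'   `stimulus_kind`, `eyebrow`, `emotion`, `window_start`, and feature
#'   columns `f1..f80`.
#' @export
mimic_feature_table <- function(windows, participant = NA) {
  feats <- t(vapply(windows, window_features, numeric(80)))
  colnames(feats) <- paste0("f", seq_len(80))
  lab <- function(field) vapply(windows, function(w) {
    v <- w$label[[field]]
    if (is.null(v) || is.na(v)) NA_character_ else as.character(v)
  }, "")
  data.frame(
    participant = participant,
    stimulus_id = lab("stimulus_id"),
    stimulus_kind = lab("stimulus_kind"),
    eyebrow = lab("eyebrow"),
    emotion = lab("emotion"),
    window_start = vapply(windows, function(w) w$start, 0),
    feats,
    stringsAsFactors = FALSE)
}

#' Z-score the feature columns of a table
#'
#' Normalizes every feature column to mean 0 and standard deviation 1.
#' Zero-variance columns cannot be scaled and pass through as all-zero
#' with a warning.
#'
#' @param table a feature table (data.frame with `f1..f80` columns) or
#'   a plain numeric matrix.
#' @return the table with feature columns standardized.
#' @export
zscore_features <- function(table) {
  is_mat <- is.matrix(table)
  X <- if (is_mat) table else feature_matrix(table)
  if (nrow(X) < 2L) stop("need at least 2 rows to z-score")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  zero <- sdv <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature column(s) set to all-zero")
    sdv[zero] <- 1
  }
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Z[, zero] <- 0
  if (is_mat) return(Z)
  table[, colnames(X)] <- Z
  table
}

# emotion -> eyebrow-group mapping used by Mode 3 and cross-mode transfer
EMOTION_GROUPS <- list(
  Neutral = c("Neutral", "Joy", "Sadness"),
  Lower = c("Anger", "Disgust"),
  Raise = c("Fear", "Surprise"))

#' Map emotions to eyebrow-based groups
#'
#' The seven basic emotions partition into three groups by the eyebrow
#' state they predominantly involve: `{Neutral, Joy, Sadness}` (neutral
#' brow), `{Anger, Disgust}` (lowered brow), `{Fear, Surprise}`
#' (raised brow). Group labels are the eyebrow states so that Mode-3
#' groups and Mode-1 classes share a label space.
#'
#' @param emotion character vector of emotion labels.
#' @return character vector of group labels
#'   (`"Neutral"`, `"Lower"`, `"Raise"`).
#' @export
emotion_group <- function(emotion) {
  map <- stats::setNames(rep(names(EMOTION_GROUPS), lengths(EMOTION_GROUPS)),
                         unlist(EMOTION_GROUPS))
  bad <- setdiff(unique(emotion[!is.na(emotion)]), names(map))
  if (length(bad)) stop("unknown emotion label(s): ", paste(bad, collapse = ", "))
  unname(map[emotion])
}

#' Assemble one of the three classification modes
#'
#' * Mode 1 — three eyebrow states `{Neutral, Lower, Raise}` from the
#'   basic-figure trials; because the basic Neutral class is smaller
#'   than Lower/Raise, the portrait Neutral trials (visually identical
#'   expression) are merged into it to balance the classes.
#' * Mode 2 — seven emotions from the portrait trials.
#' * Mode 3 — portrait trials regrouped into the three eyebrow-based
#'   emotion groups; the `{Neutral, Joy, Sadness}` group is the largest
#'   and rows are removed from it uniformly at random (seeded) until
#'   all groups are equal in size.
#'
#' @param table feature table from [mimic_feature_table()] covering
#'   both stimulus kinds.
#' @param mode 1, 2 or 3.
#' @param seed integer seed controlling the Mode-3 down-sampling.
#' @return the subset table with a `label` factor column appended.
#' @export
assemble_mode <- function(table, mode, seed = 1L) {
  stopifnot(mode %in% 1:3)
  if (mode == 1) {
    basic <- table[table$stimulus_kind == "basic", , drop = FALSE]
    if (anyNA(basic$eyebrow)) stop("basic trials with missing eyebrow labels")
    basic$label <- basic$eyebrow
    extra <- table[table$stimulus_kind == "portrait" &
                     !is.na(table$emotion) & table$emotion == "Neutral", , drop = FALSE]
    extra$label <- "Neutral"
    out <- rbind(basic, extra)
  } else {
    out <- table[table$stimulus_kind == "portrait", , drop = FALSE]
    if (anyNA(out$emotion)) stop("portrait trials with missing emotion labels")
    if (mode == 2) {
      out$label <- out$emotion
    } else {
      out$label <- emotion_group(out$emotion)
      sizes <- table(out$label)
      target <- min(sizes)
      big <- names(sizes)[which.max(sizes)]
      excess <- max(sizes) - target
      if (excess > 0) {
        idx_big <- which(out$label == big)
        drop <- with_seed(seed, sample(idx_big, excess))
        out <- out[-drop, , drop = FALSE]
      }
    }
  }
  if (nrow(out) == 0L) stop("mode ", mode, ": no rows selected")
  out$label <- factor(out$label)
  rownames(out) <- NULL
  out
}

#' Specify a classifier
#'
#' The four classifier families compared in the pipeline, with their
#' default hyperparameters:
#'
#' * `"knn"` — k-nearest neighbours, `k = 5`.
#' * `"svm"` — support vector machine with a cubic polynomial kernel
#'   (one-vs-one multiclass, unit cost).
#' * `"bagged_trees"` — bootstrap-aggregated decision trees
#'   (`n_learners = 200`).
#' * `"subspace_knn"` — ensemble of KNN learners each trained on a
#'   random feature subspace (`n_learners = 30`,
#'   `subspace_dim = 40`), majority vote.
#'
#' @param method one of the four names above.
#' @param k neighbours for `"knn"` / `"subspace_knn"`.
#' @param n_learners ensemble size for `"bagged_trees"` /
#'   `"subspace_knn"`.
#' @param subspace_dim features per learner for `"subspace_knn"`.
#' @param cost,degree,coef0 SVM cubic-kernel parameters.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(method = c("svm", "knn", "bagged_trees", "subspace_knn"),
                            k = 5L, n_learners = NULL, subspace_dim = 40L,
                            cost = 1, degree = 3L, coef0 = 1) {
  method <- match.arg(method)
  if (is.null(n_learners)) {
    n_learners <- switch(method, bagged_trees = 200L, subspace_knn = 30L, 0L)
  }
  structure(list(method = method, k = as.integer(k),
                 n_learners = as.integer(n_learners),
                 subspace_dim = as.integer(subspace_dim),
                 cost = cost, degree = as.integer(degree), coef0 = coef0),
            class = "classifier_spec")
}

# Fit spec on (X, y); returns a closure predicting factor labels.
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- factor(y)
  if (spec$method == "svm") {
    fit <- e1071::svm(X, y, kernel = "polynomial", degree = spec$degree,
                      coef0 = spec$coef0, cost = spec$cost, scale = TRUE)
    function(newX) stats::predict(fit, newX)
  } else if (spec$method == "knn") {
    sc <- scale(X)
    ctr <- attr(sc, "scaled:center"); scl <- attr(sc, "scaled:scale")
    scl[scl == 0] <- 1
    function(newX) {
      class::knn(sweep(sweep(X, 2, ctr), 2, scl, "/"),
                 sweep(sweep(newX, 2, ctr), 2, scl, "/"), y, k = spec$k)
    }
  } else if (spec$method == "bagged_trees") {
    fit <- randomForest::randomForest(X, y, ntree = spec$n_learners,
                                      mtry = ncol(X))
    function(newX) stats::predict(fit, newX)
  } else { # subspace_knn
    d <- min(spec$subspace_dim, ncol(X))
    subspaces <- lapply(seq_len(spec$n_learners),
                        function(i) sample(ncol(X), d))
    sc <- scale(X)
    ctr <- attr(sc, "scaled:center"); scl <- attr(sc, "scaled:scale")
    scl[scl == 0] <- 1
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    function(newX) {
      newXs <- sweep(sweep(newX, 2, ctr), 2, scl, "/")
      votes <- vapply(subspaces, function(s) {
        as.character(class::knn(Xs[, s, drop = FALSE],
                                newXs[, s, drop = FALSE], y, k = spec$k))
      }, character(nrow(newX)))
      if (nrow(newX) == 1L) votes <- matrix(votes, nrow = 1)
      factor(apply(votes, 1, function(v) names(which.max(table(v)))),
             levels = levels(y))
    }
  }
}

#' Build an evaluation report from predictions
#'
#' @param truth,predicted factors over the same label set.
#' @param meta optional list of run metadata (seeds, spec) echoed in
#'   the report.
#' @return object of class `eval_report`: confusion matrix (rows =
#'   truth), `accuracy`, per-class `precision` and false-negative rate
#'   `fnr`, macro `f1`.
#' @export
eval_report <- function(truth, predicted, meta = list()) {
  lev <- union(levels(factor(truth)), levels(factor(predicted)))
  truth <- factor(truth, levels = lev)
  predicted <- factor(predicted, levels = lev)
  confusion <- table(truth = truth, predicted = predicted)
  total <- sum(confusion)
  tp <- diag(confusion)
  precision <- tp / pmax(colSums(confusion), 1)
  recall <- tp / pmax(rowSums(confusion), 1)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  structure(list(confusion = confusion,
                 accuracy = sum(tp) / total,
                 precision = precision,
                 fnr = 1 - recall,
                 f1 = mean(f1),
                 n = total,
                 meta = meta),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy = %.3f, macro F1 = %.3f\n",
              x$n, x$accuracy, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Splits rows into `k` stratified folds (each class spread evenly
#' across folds), fits the classifier on each training split and pools
#' the out-of-fold predictions into a single confusion matrix.
#'
#' @param table feature table with a `label` factor column (from
#'   [assemble_mode()]) or any data.frame with `f*` columns + `label`.
#' @param spec a [classifier_spec()].
#' @param k number of folds (default 5).
#' @param seed integer seed for fold assignment (and any classifier
#'   randomness).
#' @return an `eval_report` of the pooled out-of-fold predictions.
#' @export
crossval <- function(table, spec = classifier_spec("svm"), k = 5L, seed = 1L) {
  stopifnot("label" %in% names(table))
  y <- factor(table$label)
  if (any(table(y) < k)) stop("every class needs at least k = ", k, " rows")
  X <- feature_matrix(table)
  folds <- integer(nrow(X))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    pred <- factor(rep(NA_character_, nrow(X)), levels = levels(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      model <- fit_classifier(spec, X[tr, , drop = FALSE], y[tr])
      pred[!tr] <- model(X[!tr, , drop = FALSE])
    }
    eval_report(y, pred, meta = list(spec = spec, k = k, seed = seed))
  })
}

#' Cross-mode transfer evaluation
#'
#' Fits the classifier on the full Mode-1 table (eyebrow states) and
#' predicts the Mode-3 table, scoring predictions against the
#' eyebrow-based group labels (which share the Mode-1 label space via
#' [emotion_group()]). This tests whether a model trained on simple
#' instructed eyebrow actions transfers to full-face emotional
#' expressions.
#'
#' @param train Mode-1 feature table (`label` = eyebrow state).
#' @param test Mode-3 feature table (`label` = eyebrow-based group).
#' @param spec a [classifier_spec()]; the pipeline default is the
#'   cubic-kernel SVM.
#' @param seed seed for any classifier randomness.
#' @return an `eval_report`.
#' @export
cross_mode_transfer <- function(train, test, spec = classifier_spec("svm"),
                                seed = 1L) {
  if (nrow(test) == 0L) stop("empty test table")
  y_train <- factor(train$label)
  y_test <- factor(test$label, levels = levels(y_train))
  if (anyNA(y_test)) {
    stop("test labels outside the training label space: ",
         paste(setdiff(unique(test$label), levels(y_train)), collapse = ", "))
  }
  with_seed(seed, {
    model <- fit_classifier(spec, feature_matrix(train), y_train)
    pred <- model(feature_matrix(test))
    eval_report(y_test, pred, meta = list(spec = spec, seed = seed))
  })
}
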