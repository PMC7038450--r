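# Build a feature table with the exact protocol label multiset of a
# cohort, without simulating streams: class structure is what these
# tests exercise. Feature columns carry class-dependent signal so the
# classifiers have something to learn.
label_table <- function(n_participants = 2, seed = 1, n_features = 10,
                        class_shift = 3) {
  basic <- data.frame(
    eyebrow = rep(c("Neutral", "Lower", "Raise"), times = c(40, 60, 60)),
    emotion = NA_character_, stimulus_kind = "basic")
  portrait <- data.frame(
    eyebrow = NA_character_,
    emotion = rep(c("Neutral", "Joy", "Disgust", "Fear", "Anger",
                    "Sadness", "Surprise"), each = 20),
    stimulus_kind = "portrait")
  one <- rbind(basic, portrait)
  df <- do.call(rbind, lapply(seq_len(n_participants), function(i) {
    out <- one
    out$participant <- sprintf("P%02d", i)
    out
  }))
  withr::with_seed(seed, {
    cls <- ifelse(df$stimulus_kind == "basic", df$eyebrow,
                  emotion_group(df$emotion))
    mu <- class_shift * match(cls, c("Neutral", "Lower", "Raise"))
    feats <- matrix(rnorm(nrow(df) * n_features), nrow(df)) + mu
    colnames(feats) <- paste0("f", seq_len(n_features))
    cbind(df, feats)
  })
}

test_that("z-scoring centers and scales every feature column", {
  tab <- label_table(seed = 3)
  z <- zscore_features(tab)
  X <- as.matrix(z[, paste0("f", 1:10)])
  expect_true(all(abs(colMeans(X)) < 1e-9))
  expect_true(all(abs(apply(X, 2, sd) - 1) < 1e-9))
  # constant columns pass through as zero with a warning
  tab$f1 <- 5
  expect_warning(z2 <- zscore_features(tab), "zero-variance")
  expect_true(all(z2$f1 == 0))
  expect_error(zscore_features(tab[1, , drop = FALSE]), "at least 2")
})

test_that("mode assembly reproduces the protocol class counts", {
  tab <- label_table(n_participants = 20)
  m1 <- assemble_mode(tab, 1, seed = 9)
  expect_equal(as.vector(table(m1$label)), rep(1200L, 3))
  m2 <- assemble_mode(tab, 2, seed = 9)
  expect_equal(as.vector(table(m2$label)), rep(400L, 7))
  m3 <- assemble_mode(tab, 3, seed = 9)
  expect_equal(as.vector(table(m3$label)), rep(800L, 3))
})

test_that("mode-3 balancing removes rows only from the largest group", {
  tab <- label_table(n_participants = 2)
  m3 <- assemble_mode(tab, 3, seed = 4)
  full <- table(emotion_group(tab$emotion[tab$stimulus_kind == "portrait"]))
  kept <- table(m3$label)
  expect_equal(as.vector(kept), rep(min(full), 3))
  # smaller groups are untouched
  expect_equal(kept[["Lower"]], full[["Lower"]])
  expect_equal(kept[["Raise"]], full[["Raise"]])
  # seeded removal is deterministic
  m3b <- assemble_mode(tab, 3, seed = 4)
  expect_identical(m3$f1, m3b$f1)
  m3c <- assemble_mode(tab, 3, seed = 5)
  expect_false(identical(m3$f1, m3c$f1))
})

test_that("the emotion-group mapping partitions the seven emotions", {
  emotions <- c("Neutral", "Joy", "Disgust", "Fear", "Anger", "Sadness",
                "Surprise")
  groups <- emotion_group(emotions)
  expect_length(groups, 7)
  expect_false(anyNA(groups))
  expect_equal(sort(unique(groups)), c("Lower", "Neutral", "Raise"))
  expect_equal(as.vector(table(groups)[c("Neutral", "Lower", "Raise")]),
               c(3L, 2L, 2L))
  expect_error(emotion_group("Boredom"), "unknown emotion")
})

test_that("cross-validation is perfect on separable blobs for all classifiers", {
  tab <- label_table(n_participants = 2, class_shift = 12, seed = 6)
  tab$label <- factor(ifelse(tab$stimulus_kind == "basic", tab$eyebrow,
                             emotion_group(tab$emotion)))
  for (m in c("knn", "svm", "bagged_trees", "subspace_knn")) {
    spec <- classifier_spec(m, n_learners = if (m == "bagged_trees") 50L else NULL,
                            subspace_dim = 5L)
    r <- crossval(tab, spec, k = 5, seed = 2)
    expect_gte(r$accuracy, 0.99)
  }
})

test_that("permuted labels give chance-level accuracy", {
  tab <- label_table(n_participants = 10, class_shift = 3, seed = 8)
  tab$label <- factor(ifelse(tab$stimulus_kind == "basic", tab$eyebrow,
                             emotion_group(tab$emotion)))
  tab$label <- withr::with_seed(31, sample(tab$label))
  r <- crossval(tab, classifier_spec("knn"), k = 5, seed = 2)
  expect_lt(abs(r$accuracy - 1 / 3), 0.05)
})

test_that("evaluation reports conserve counts and handle relabeling", {
  truth <- factor(rep(c("a", "b", "c"), times = c(5, 3, 2)))
  pred <- factor(c("a", "a", "a", "b", "c", "b", "b", "c", "c", "a"),
                 levels = levels(truth))
  r <- eval_report(truth, pred)
  expect_equal(unname(rowSums(r$confusion)), c(5, 3, 2))
  expect_equal(r$accuracy, sum(diag(r$confusion)) / 10)
  # accuracy invariant under a consistent class permutation
  perm <- c(a = "b", b = "c", c = "a")
  r2 <- eval_report(factor(perm[as.character(truth)]),
                    factor(perm[as.character(pred)]))
  expect_equal(r2$accuracy, r$accuracy)
})

test_that("cross-mode transfer scores mapped group labels", {
  tab <- label_table(n_participants = 2, class_shift = 12, seed = 10)
  m1 <- assemble_mode(tab, 1, seed = 1)
  m3 <- assemble_mode(tab, 3, seed = 1)
  r <- cross_mode_transfer(m1, m3, classifier_spec("knn"), seed = 1)
  expect_gte(r$accuracy, 0.99)
  expect_error(cross_mode_transfer(m1, m3[0, , drop = FALSE]), "empty test")
  bad <- m3; bad$label <- "Elsewhere"
  expect_error(cross_mode_transfer(m1, bad), "label")
})

test_that("fold assignment is seeded and reproducible", {
  tab <- label_table(n_participants = 2, seed = 12)
  tab$label <- factor(ifelse(tab$stimulus_kind == "basic", tab$eyebrow,
                             emotion_group(tab$emotion)))
  r1 <- crossval(tab, classifier_spec("knn"), seed = 5)
  r2 <- crossval(tab, classifier_spec("knn"), seed = 5)
  expect_identical(r1$confusion, r2$confusion)
})
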