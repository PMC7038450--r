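test_that("histogram pairs match a loop-based binning oracle", {
  withr::with_seed(21, {
    values <- rnorm(500)
    mask <- runif(500) < 0.4
  })
  pair <- paired_histograms(values, mask)
  expect_equal(pair$counts_a, oracle_bin_counts(values[mask]))
  expect_equal(pair$counts_b, oracle_bin_counts(values[!mask]))
  expect_length(pair$edges, 27)
})

test_that("out-of-range values are clipped into the edge bins", {
  pair <- paired_histograms(c(3.5, -9, 0, 0.01), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(pair$counts_a[26], 1)  # 3.5 -> last bin
  expect_equal(pair$counts_a[1], 1)   # -9 -> first bin
  expect_equal(sum(pair$counts_b[13:14]), 2)  # values at 0 stay central
  expect_error(paired_histograms(1:3, c(FALSE, FALSE, FALSE), "C1"),
               "empty group under C1")
})

test_that("balancing equalizes sums and preserves shape", {
  pair <- paired_histograms(c(rep(-1, 100), rep(1, 300)),
                            c(rep(TRUE, 100), rep(FALSE, 300)))
  bal <- balance_pair(pair, 400)
  expect_equal(sum(bal$counts_a), 200, tolerance = 1e-9)
  expect_equal(sum(bal$counts_b), 200, tolerance = 1e-9)
  # idempotent on an already balanced pair
  again <- balance_pair(bal, 400)
  expect_equal(again$counts_a, bal$counts_a)
  # nonzero-bin ratios unchanged
  nz <- pair$counts_a > 0
  expect_equal(bal$counts_a[nz] / sum(bal$counts_a),
               pair$counts_a[nz] / sum(pair$counts_a))
})

test_that("chi-square statistic matches hand computations", {
  same <- paired_histograms(rep(c(-1, 0, 1), 20), rep(c(TRUE, FALSE), 30))
  bal <- balance_pair(same, 60)
  r0 <- chi_square_pair(balance_pair(
    paired_histograms(rep(0, 40), rep(c(TRUE, FALSE), 20)), 40))
  expect_equal(r0$cv, 0)
  expect_equal(r0$p, 1)
  # toy pair: a = [150, 50], b = [50, 150] -> CV = 100
  toy <- structure(list(edges = seq(-2, 2, length.out = 27),
                        counts_a = c(150, 50, rep(0, 24)),
                        counts_b = c(50, 150, rep(0, 24)),
                        balanced = TRUE),
                   class = "hist_pair")
  r <- chi_square_pair(toy)
  expect_equal(r$cv, 100)
  expect_equal(r$df, 25)
  expect_equal(r$p, pchisq(100, 25, lower.tail = FALSE))
  # symmetry in (a, b)
  swapped <- toy
  swapped$counts_a <- toy$counts_b
  swapped$counts_b <- toy$counts_a
  expect_equal(chi_square_pair(swapped)$cv, r$cv)
  # unbalanced pairs are rejected
  un <- toy; un$balanced <- FALSE; un$counts_a <- un$counts_a * 2
  expect_error(chi_square_pair(un), "not balanced")
})

test_that("the chi-square scan keeps its type-I error near alpha", {
  reps <- 500
  hits <- withr::with_seed(77, vapply(seq_len(reps), function(i) {
    values <- rnorm(400)
    mask <- runif(400) < 0.5
    if (!any(mask) || all(mask)) return(FALSE)
    pair <- balance_pair(paired_histograms(values, mask), 400)
    chi_square_pair(pair)$p < 0.05
  }, TRUE))
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("the condition scan finds a planted signal and reports 8 rows", {
  withr::with_seed(33, {
    n <- 600
    X <- matrix(rnorm(n * 80), n, 80)
    colnames(X) <- paste0("f", 1:80)
    masks <- matrix(runif(n * 8) < 0.5, n, 8,
                    dimnames = list(NULL, paste0("C", 1:8)))
    X[masks[, 3], 48] <- X[masks[, 3], 48] + 1  # planted shift under C3
  })
  out <- condition_scan(zscore_features(X), masks)
  expect_equal(nrow(out), 8)
  expect_equal(out$best_feature[3], 48)
  expect_lt(out$p[3], 0.001)
  # pure-noise conditions flag about alpha * 80 features
  expect_lt(max(out$n_significant[-3]), 12)
})

test_that("empty condition groups are skipped, not fatal", {
  X <- matrix(rnorm(200), 100, 2)
  masks <- cbind(C1 = rep(FALSE, 100), C2 = runif(100) < 0.5)
  out <- condition_scan(X, masks)
  expect_true(out$skipped[1])
  expect_false(out$skipped[2])
  expect_true(is.na(out$cv[1]))
})

test_that("session aggregation matches a loop oracle and its conventions", {
  withr::with_seed(5, X <- matrix(rnorm(21 * 80), 21, 80))
  colnames(X) <- paste0("f", 1:80)
  got <- session_features(X)
  expect_length(got, 320)
  for (j in c(1, 17, 80)) {
    v <- X[, j]
    m2 <- mean((v - mean(v))^2)
    expect_equal(unname(got[(j - 1) * 4 + 1:4]),
                 c(mean(v), sd(v), max(v) - min(v),
                   mean((v - mean(v))^4) / m2^2 - 3),
                 tolerance = 1e-9)
  }
  # constant feature: sd = range = 0, kurtosis defined as 0
  X[, 1] <- 2.5
  got2 <- session_features(X)
  expect_equal(unname(got2[1:4]), c(2.5, 0, 0, 0))
  expect_error(session_features(X[1:2, ]), "at least 4")
})

test_that("median-split evaluation is deterministic and checks degeneracy", {
  withr::with_seed(12, {
    n_ses <- 40
    ses <- matrix(rnorm(n_ses * 20), n_ses, 20)
    scores <- runif(n_ses)
    pid <- rep(sprintf("P%02d", 1:8), each = 5)
    expressiveness <- setNames(seq(0, 1, length.out = 8), sprintf("P%02d", 1:8))
    ses[scores > median(scores), 1:5] <- ses[scores > median(scores), 1:5] + 2
  })
  spec <- classifier_spec("subspace_knn", subspace_dim = 10)
  r1 <- median_split_eval(ses, scores, pid, expressiveness, spec = spec, seed = 3)
  r2 <- median_split_eval(ses, scores, pid, expressiveness, spec = spec, seed = 3)
  expect_identical(r1$all$confusion, r2$all$confusion)
  # classes balanced within one either side of the median
  expect_lte(abs(sum(scores > median(scores)) - sum(scores <= median(scores))), 1)
  expect_gt(r1$all$accuracy, 0.8)  # strong planted separation
  expect_error(median_split_eval(ses, rep(1, n_ses), pid, expressiveness),
               "degenerate")
})
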