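test_that("rank-statistic AUC matches the exhaustive pairwise count", {
  # perfect separation and reversal
  p <- scored_predictions(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(auc_rank(p), 1)
  p <- scored_predictions(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_equal(auc_rank(p), 0)
  set.seed(11)
  for (i in 1:50) {
    n <- sample(8:20, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # forces ties
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    expect_equal(auc_rank(scores, labels), oracle_auc_pairs(scores, labels))
  }
})

test_that("AUC is invariant under monotone transforms and flips with labels", {
  set.seed(12)
  for (i in 1:20) {
    scores <- rnorm(30)
    labels <- c(1, 0, rbinom(28, 1, 0.4))
    a <- auc_rank(scores, labels)
    expect_equal(auc_rank(exp(scores), labels), a)
    expect_equal(auc_rank(qlogis(plogis(scores)), labels), a, tolerance = 1e-12)
    expect_equal(auc_rank(scores, 1 - labels), 1 - a)
  }
  expect_error(auc_rank(c(1, 2, 3), c(1, 1, 1)), "undefined")
})

test_that("classification metrics follow their defining formulas", {
  m <- classification_metrics(list(tp = 3, tn = 2, fp = 1, fn = 2))
  expect_equal(m$accuracy, 0.625)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(round(m$f1, 4), 0.6667)
  all_correct <- classification_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_true(all(all_correct == 1))
  set.seed(13)
  for (i in 1:100) {
    cts <- as.list(stats::setNames(sample(1:30, 4, replace = TRUE),
                                   c("tp", "tn", "fp", "fn")))
    m <- classification_metrics(cts)
    expect_equal(m$f1, 2 * cts$tp / (2 * cts$tp + cts$fp + cts$fn))
  }
})

test_that("undefined metrics are NA with a warning, never zero", {
  expect_warning(m <- classification_metrics(list(tp = 0, tn = 5, fp = 0, fn = 3)),
                 "precision")
  expect_true(is.na(m$precision))
  expect_false(identical(m$precision, 0))
})

test_that("threshold confusion partitions the sample", {
  scores <- c(0.1, 0.3, 0.45, 0.5, 0.55, 0.6, 0.7, 0.8, 0.9, 0.95)
  labels <- c(0, 0, 1, 0, 1, 0, 1, 1, 0, 1)
  cm <- threshold_confusion(scores, labels, threshold = 0.5)
  # hand count: predicted positive are scores >= 0.5 (7 of them)
  expect_equal(cm$tp, 4); expect_equal(cm$fp, 3)
  expect_equal(cm$tn, 2); expect_equal(cm$fn, 1)
  lo <- threshold_confusion(scores, labels, threshold = 0)
  expect_equal(lo$fn + lo$tn, 0)
  hi <- threshold_confusion(scores, labels, threshold = 2)
  expect_equal(hi$tp + hi$fp, 0)
})

test_that("DeLong test handles degenerate and symmetric cases", {
  set.seed(14)
  labels <- rbinom(60, 1, 0.5); labels[1:2] <- c(0, 1)
  s <- rnorm(60) + labels
  pa <- scored_predictions(s, labels)
  same <- delong_test(pa, pa)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  s2 <- rnorm(60) + 0.5 * labels
  pb <- scored_predictions(s2, labels)
  ab <- delong_test(pa, pb)
  ba <- delong_test(pb, pa)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$auc_a, auc_rank(pa))
})

test_that("DeLong variance agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  for (i in 1:10) {
    labels <- c(0, 1, rbinom(98, 1, 0.5))
    sa <- rnorm(100) + labels
    sb <- 0.7 * sa + rnorm(100, sd = 0.5)
    ours <- delong_test(scored_predictions(sa, labels),
                        scored_predictions(sb, labels))
    ref <- pROC::roc.test(pROC::roc(labels, sa, quiet = TRUE),
                          pROC::roc(labels, sb, quiet = TRUE),
                          method = "delong")
    expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("DeLong p-value agrees with a paired-bootstrap oracle", {
  set.seed(16)
  n <- 200
  labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
  sa <- rnorm(n) + 1.0 * labels
  sb <- rnorm(n) + 0.8 * labels
  ours <- delong_test(scored_predictions(sa, labels),
                      scored_predictions(sb, labels))
  nboot <- 10000
  deltas <- numeric(nboot)
  for (b in seq_len(nboot)) {
    idx <- sample.int(n, replace = TRUE)
    if (length(unique(labels[idx])) < 2) { deltas[b] <- NA; next }
    deltas[b] <- auc_rank(sa[idx], labels[idx]) - auc_rank(sb[idx], labels[idx])
  }
  deltas <- deltas[!is.na(deltas)]
  p_boot <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
  expect_lt(abs(ours$p - p_boot), 0.03)
})

test_that("chi-square test matches the O/E summation and known df", {
  flat <- matrix(c(10, 20, 30, 60), 2, byrow = TRUE) # identical proportions
  res <- chi_square_test(flat)
  expect_equal(res$stat, 0)
  expect_equal(res$p, 1)
  expect_equal(chi_square_test(matrix(5, 2, 4))$df, 3)
  set.seed(17)
  for (i in 1:30) {
    tab <- matrix(sample(5:40, 4), 2, 2)
    res <- chi_square_test(tab)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$stat, sum((tab - e)^2 / e), tolerance = 1e-10)
  }
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "empty row")
})

test_that("Welch t-test matches the textbook formula and is scale invariant", {
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 4)
  res <- welch_t_test(a, b)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  set.seed(18)
  for (i in 1:20) {
    a <- rnorm(sample(5:15, 1)); b <- rnorm(sample(5:15, 1), mean = 0.5)
    res <- welch_t_test(a, b)
    se2 <- var(a) / length(a) + var(b) / length(b)
    t_manual <- (mean(a) - mean(b)) / sqrt(se2)
    df_manual <- se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                          (var(b) / length(b))^2 / (length(b) - 1))
    expect_equal(res$t, t_manual, tolerance = 1e-10)
    expect_equal(res$df, df_manual, tolerance = 1e-10)
    res_scaled <- welch_t_test(3 * a, 3 * b)
    expect_equal(res_scaled$t, res$t, tolerance = 1e-10)
  }
})

test_that("cohort summary reproduces category percentages from counts", {
  # cohort with the tumor-type composition 72 EP / 159 MB / 109 PA of 340
  df <- data.frame(type = rep(c("EP", "MB", "PA"), c(72, 159, 109)))
  cs <- cohort_summary(df, "type")
  expect_equal(cs$pct[cs$level == "EP"], 21.2)
  expect_equal(cs$pct[cs$level == "MB"], 46.8)
  expect_equal(cs$pct[cs$level == "PA"], 32.1)
  single <- cohort_summary(data.frame(g = rep("x", 7)), "g")
  expect_equal(single$pct, 100.0)
  expect_error(cohort_summary(data.frame(g = character(0)), "g"), "empty")
})
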