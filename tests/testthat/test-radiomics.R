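test_that("first-order features match scalar-loop moments", {
  # constant region: zero variance/entropy, flagged skewness
  vol <- array(3, c(4, 4, 4)); mask <- array(1, c(4, 4, 4))
  f <- first_order_features(vol, mask)
  expect_equal(f$variance, 0)
  expect_equal(f$entropy, 0)
  expect_equal(f$skewness, 0)
  expect_true(f$degenerate)
  # two voxels {0, 2}: population variance
  vol2 <- array(0, c(2, 1, 1)); vol2[2] <- 2
  mask2 <- array(1, c(2, 1, 1))
  f2 <- first_order_features(vol2, mask2)
  expect_equal(f2$mean, 1)
  expect_equal(f2$variance, 1)
  # random region against explicit loops
  set.seed(61)
  vol3 <- array(rnorm(8^3), c(8, 8, 8))
  mask3 <- array(rbinom(8^3, 1, 0.4), c(8, 8, 8))
  f3 <- first_order_features(vol3, mask3, voxel_volume = 2.5)
  xs <- c(); n <- 0
  for (k in 1:8) for (j in 1:8) for (i in 1:8) {
    if (mask3[i, j, k] == 1) { xs <- c(xs, vol3[i, j, k]); n <- n + 1 }
  }
  mu <- sum(xs) / n
  v <- sum((xs - mu)^2) / n
  expect_equal(f3$mean, mu, tolerance = 1e-10)
  expect_equal(f3$variance, v, tolerance = 1e-10)
  expect_equal(f3$skewness, sum((xs - mu)^3) / n / v^1.5, tolerance = 1e-10)
  expect_equal(f3$kurtosis, sum((xs - mu)^4) / n / v^2, tolerance = 1e-10)
  expect_equal(f3$energy, sum(xs^2), tolerance = 1e-10)
  expect_equal(f3$voxel_count, n)
  expect_equal(f3$volume, n * 2.5)
  expect_error(first_order_features(vol3, array(0, c(8, 8, 8))), "empty mask")
})

test_that("feature names carry the sequence prefix", {
  vol <- array(rnorm(27), c(3, 3, 3)); mask <- array(1, c(3, 3, 3))
  f <- first_order_features(vol, mask, prefix = "ADC")
  expect_true(all(startsWith(names(f), "ADC_firstorder_")))
})

test_that("chi-square filter passes signal and rejects constants", {
  set.seed(62)
  labels <- rep(c(0, 1), each = 50)
  x <- data.frame(signal = labels + rnorm(100, sd = 0.01),
                  noise = rnorm(100),
                  flat = rep(1, 100))
  res <- suppressWarnings(chi2_filter(x, labels))
  expect_true(res$pass[res$feature == "signal"])
  expect_false(res$pass[res$feature == "flat"])
  expect_equal(res$p[res$feature == "flat"], 1)
  expect_warning(chi2_filter(x["flat"], labels), "unsplittable")
})

test_that("chi-square filter type-I error tracks alpha on null features", {
  set.seed(63)
  labels <- rep(c(0, 1), each = 100)
  null_x <- matrix(rnorm(200 * 1000), nrow = 200)
  colnames(null_x) <- paste0("f", 1:1000)
  res <- chi2_filter(null_x, labels, alpha = 0.05)
  expect_gt(mean(res$pass), 0.03)
  expect_lt(mean(res$pass), 0.07)
})

test_that("LASSO selection recovers planted features and shrinks to empty", {
  set.seed(64)
  n <- 300; p <- 50
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0(rep(c("ADC", "T2WI"), length.out = p), "_f", 1:p)
  beta <- rep(0, p); beta[1:5] <- c(1.5, -1.5, 1.2, -1.2, 1.0)
  pr <- 1 / (1 + exp(-(x %*% beta)))
  y <- rbinom(n, 1, pr)
  res <- lasso_select(x, y, folds = 5, seed = 1)
  hits <- sum(res$coefficients$selected[1:5])
  expect_gte(hits, 4)
  # the largest lambda on the path shrinks everything away
  expect_equal(unname(res$nonzero_path[1]), 0)
  # selected-set size grows as lambda shrinks (coordinate descent may swap
  # the odd variable in and out locally, so exact monotonicity is not forced)
  nz <- as.numeric(res$nonzero_path)
  expect_true(all(diff(nz) >= -2))
  expect_gt(nz[length(nz)], nz[1])
  expect_true(all(nz[1:5] <= nz[length(nz)]))
  expect_error(lasso_select(x[1:3, ], y[1:3], folds = 5), "fewer samples")
})

test_that("selection is invariant to column scaling", {
  set.seed(65)
  n <- 200; p <- 20
  agree <- 0
  for (rep_i in 1:5) {
    x <- matrix(rnorm(n * p), n, p)
    colnames(x) <- paste0("seq_f", 1:p)
    y <- rbinom(n, 1, 1 / (1 + exp(-(1.5 * x[, 1] - 1.5 * x[, 2]))))
    a <- lasso_select(x, y, seed = rep_i)
    x2 <- x; x2[, 1] <- 10 * x2[, 1]
    b <- lasso_select(x2, y, seed = rep_i)
    if (identical(a$coefficients$selected, b$coefficients$selected)) {
      agree <- agree + 1
    }
  }
  expect_gte(agree, 4)
})

test_that("feature ranking is by absolute coefficient with stable ties", {
  res <- structure(list(coefficients = tibble::tibble(
    feature = c("ADC_a", "T2WI_b", "FLAIR_c", "ADC_d"),
    coefficient = c(0.5, -0.9, 0, 0.5),
    selected = c(TRUE, TRUE, FALSE, TRUE))), class = "cvit_selection")
  rk <- rank_features(res)
  expect_equal(rk$feature, c("T2WI_b", "ADC_a", "ADC_d"))
  expect_equal(rk$sequence, c("T2WI", "ADC", "ADC"))
  expect_equal(nrow(rank_features(res, top_k = 100)), 3)
  # per-sequence tally conserves the selected-feature count
  expect_equal(sum(table(rk$sequence)), sum(res$coefficients$selected))
  empty <- structure(list(coefficients = tibble::tibble(
    feature = "x", coefficient = 0, selected = FALSE)),
    class = "cvit_selection")
  expect_equal(nrow(rank_features(empty)), 0)
})

test_that("phantom-derived features separate the grades linearly", {
  batch <- generate_phantom_dataset(60, seed = 66)
  feats <- t(vapply(seq_along(batch$volumes), function(i) {
    v <- batch$volumes[[i]]; m <- batch$masks[[i]]
    c(adc_mean = first_order_features(v[, , , 5], m)$mean,
      t2_var = first_order_features(v[, , , 3], m)$variance)
  }, numeric(2)))
  df <- data.frame(feats, y = batch$labels)
  fit <- suppressWarnings(glm(y ~ adc_mean + t2_var, data = df, family = binomial))
  acc <- mean((fitted(fit) >= 0.5) == (df$y == 1))
  expect_gte(acc, 0.9)
})
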