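rand_map <- function(d, h, w, c, seed = 1) {
  set.seed(seed)
  array(rnorm(d * h * w * c), c(d, h, w, c))
}

test_that("grouped 3D convolution matches the scalar-loop oracle", {
  set.seed(21)
  cases <- list(
    list(dims = c(3, 4, 4, 2), k = 3, cg = 2, co = 3, stride = 1, pad = 1, groups = 1),
    list(dims = c(4, 4, 4, 4), k = 3, cg = 1, co = 4, stride = 1, pad = 1, groups = 4),
    list(dims = c(4, 5, 3, 6), k = 1, cg = 2, co = 9, stride = 1, pad = 0, groups = 3),
    list(dims = c(5, 5, 5, 2), k = 3, cg = 2, co = 2, stride = 2, pad = 1, groups = 1)
  )
  for (cs in cases) {
    x <- array(rnorm(prod(cs$dims)), cs$dims)
    w <- array(rnorm(cs$k^3 * cs$cg * cs$co), c(cs$k, cs$k, cs$k, cs$cg, cs$co))
    b <- rnorm(cs$co)
    got <- cvit3d:::conv3d(x, w, b, stride = cs$stride, pad = cs$pad,
                           groups = cs$groups)
    want <- oracle_conv3d(x, w, b, stride = cs$stride, pad = cs$pad,
                          groups = cs$groups)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("SE block: identity scaling, zero input, and scalar oracle", {
  x <- rand_map(4, 4, 4, 2, seed = 22)
  p <- cvit3d:::se_init(2, 2)
  # saturate the output sigmoid so every excitation weight is exactly 1
  p_sat <- p; p_sat$w2[] <- 0; p_sat$b2[] <- 50
  res <- se_forward(x, p_sat, reduction = 2)
  expect_identical(res$weights, c(1, 1))
  expect_equal(res$output, x)
  # zero input stays zero whatever the weights
  z <- se_forward(array(0, dim(x)), p, reduction = 2)
  expect_true(all(z$output == 0))
  # random case against the hand-rolled pool -> perceptron -> sigmoid -> scale
  res <- se_forward(x, p, reduction = 2)
  want <- oracle_se(x, p)
  expect_equal(res$output, want$y, tolerance = 1e-6)
  expect_equal(res$weights, want$weights, tolerance = 1e-6)
  expect_true(all(res$weights > 0 & res$weights < 1))
  expect_error(se_forward(rand_map(2, 2, 2, 3), p, reduction = 2),
               "not divisible")
})

test_that("gating network: sigmoid endpoints and determinism", {
  x <- rand_map(3, 4, 4, 3, seed = 23)
  p0 <- list(w = matrix(0, 3, 3), b = rep(0, 3))
  expect_equal(gate_forward(x, p0), rep(0.5, 3))
  p_hi <- list(w = matrix(0, 3, 3), b = rep(100, 3))
  expect_equal(gate_forward(x, p_hi), rep(1, 3))
  # matches the explicit pooled-affine-sigmoid computation
  set.seed(24)
  p <- list(w = matrix(rnorm(9), 3, 3), b = rnorm(3))
  z <- vapply(1:3, function(c) mean(x[, , , c]), numeric(1))
  want <- 1 / (1 + exp(-(drop(z %*% p$w) + p$b)))
  expect_equal(gate_forward(x, p), want, tolerance = 1e-6)
  expect_identical(gate_forward(x, p), gate_forward(x, p))
  xbad <- x; xbad[1] <- NaN
  expect_error(gate_forward(xbad, p), "non-finite")
})

test_that("separable grouped convolution: identity, gcd degeneracy, oracle", {
  # identity: 4 -> 4 channels, K = 1 kernels all one, no bias
  x <- rand_map(3, 3, 3, 4, seed = 25)
  p <- cvit3d:::dsgc_init(4L, 4L, k = 1L)
  p$dw$w[] <- 1; p$dw$b[] <- 0
  p$pw$w[] <- 1; p$pw$b[] <- 0 # gcd = 4, one input channel per group
  expect_equal(dsgc_forward(x, p, stride = 1, pad = 0), x)
  # gcd = 1: pointwise stage is an ordinary convolution over all channels
  x2 <- rand_map(3, 3, 3, 2, seed = 26)
  p2 <- cvit3d:::dsgc_init(2L, 3L)
  mid <- cvit3d:::conv3d(x2, p2$dw$w, p2$dw$b, stride = 1, pad = 1, groups = 2)
  want <- oracle_conv3d(mid, p2$pw$w, p2$pw$b, stride = 1, pad = 0, groups = 1)
  expect_equal(dsgc_forward(x2, p2), want, tolerance = 1e-12)
  # random 6 -> 9 case against the two-stage oracle composition
  x3 <- rand_map(4, 4, 4, 6, seed = 27)
  p3 <- cvit3d:::dsgc_init(6L, 9L)
  mid3 <- oracle_conv3d(x3, p3$dw$w, p3$dw$b, stride = 1, pad = 1, groups = 6)
  want3 <- oracle_conv3d(mid3, p3$pw$w, p3$pw$b, stride = 1, pad = 0, groups = 3)
  expect_equal(dsgc_forward(x3, p3), want3, tolerance = 1e-5)
})

test_that("extraction stage equals modulate-then-convolve composition", {
  x <- rand_map(4, 4, 4, 4, seed = 28)
  set.seed(29)
  p <- cvit3d:::msfe_init(4L, 6L)
  # gates forced to 1: plain separable convolution
  p1 <- p; p1$gn$w[] <- 0; p1$gn$b[] <- 100
  expect_equal(msfe_forward(x, p1)$output, dsgc_forward(x, p1$dsgc))
  # gates forced to 0: bias-only response to the zero tensor
  p0 <- p; p0$gn$w[] <- 0; p0$gn$b[] <- -100
  expect_equal(msfe_forward(x, p0)$output,
               dsgc_forward(array(0, dim(x)), p0$dsgc))
  # random gates: explicit composition
  g <- gate_forward(x, p$gn)
  xm <- sweep(x, 4, g, `*`)
  expect_equal(msfe_forward(x, p)$output, dsgc_forward(xm, p$dsgc),
               tolerance = 1e-5)
})

test_that("fusion stem recovers each routing endpoint exactly", {
  cfg <- tiny_config()
  set.seed(30)
  params <- cvit3d:::caeff_init(cfg)
  x <- rand_map(6, 8, 8, 5, seed = 31)
  force_gates <- function(p, b) {
    for (c in c(1, 3, 4, 5)) { p[[c]]$gate$w[] <- 0; p[[c]]$gate$b[] <- b }
    p
  }
  p_std <- force_gates(params, 100)  # g = 1: standard-convolution path
  p_sep <- force_gates(params, -100) # g = 0: separable path
  out_std <- caeff_forward(x, p_std, stride = 2)
  out_sep <- caeff_forward(x, p_sep, stride = 2)
  cs <- cfg$stem_channels
  for (c in c(1, 3, 4, 5)) {
    xc <- array(x[, , , c], c(6, 8, 8, 1))
    idx <- ((c - 1) * cs + 1):(c * cs)
    conv_path <- cvit3d:::conv3d(xc, params[[c]]$conv$w, params[[c]]$conv$b,
                                 stride = 2, pad = 1)
    sep_path <- dsgc_forward(xc, params[[c]]$dsgc, stride = 2, pad = 1)
    expect_equal(out_std$output[, , , idx], conv_path[, , , ], tolerance = 1e-12)
    expect_equal(out_sep$output[, , , idx], sep_path[, , , ], tolerance = 1e-12)
  }
  # convex blend: every voxel lies between the two endpoints
  out <- caeff_forward(x, params, stride = 2)
  for (c in c(1, 3, 4, 5)) {
    idx <- ((c - 1) * cs + 1):(c * cs)
    lo <- pmin(out_std$output[, , , idx], out_sep$output[, , , idx])
    hi <- pmax(out_std$output[, , , idx], out_sep$output[, , , idx])
    expect_true(all(out$output[, , , idx] >= lo - 1e-10))
    expect_true(all(out$output[, , , idx] <= hi + 1e-10))
  }
  expect_true(all(out$gates > 0 & out$gates < 1))
  expect_error(caeff_forward(rand_map(6, 8, 8, 4), params), "5 input channels")
})

test_that("hard routing snaps each gate to a single path", {
  cfg <- tiny_config()
  set.seed(32)
  params <- cvit3d:::caeff_init(cfg)
  x <- rand_map(6, 8, 8, 5, seed = 33)
  soft <- caeff_forward(x, params, stride = 2)
  hard <- caeff_forward(x, params, stride = 2, hard_gates = TRUE,
                        threshold = 0.5)
  cs <- cfg$stem_channels
  for (i in seq_along(soft$gates)) {
    c <- c(1, 3, 4, 5)[i]
    idx <- ((c - 1) * cs + 1):(c * cs)
    xc <- array(x[, , , c], c(6, 8, 8, 1))
    want <- if (soft$gates[i] >= 0.5) {
      cvit3d:::conv3d(xc, params[[c]]$conv$w, params[[c]]$conv$b,
                      stride = 2, pad = 1)
    } else {
      dsgc_forward(xc, params[[c]]$dsgc, stride = 2, pad = 1)
    }
    expect_equal(hard$output[, , , idx], want[, , , ], tolerance = 1e-12)
  }
})
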