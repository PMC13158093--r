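test_that("output shape follows the sliding-window rule and matches enumeration", {
  # same-padding identity
  sp <- conv_spec(k1 = 3, pad = 1, stride = 1)
  expect_equal(conv_output_shape(c(5, 5, 5), sp), c(5L, 5L, 5L))
  # 1x1x1 kernel is shape-preserving
  sp1 <- conv_spec(k1 = 1, pad = 0, stride = 1)
  expect_equal(conv_output_shape(c(4, 7, 9), sp1), c(4L, 7L, 9L))
  set.seed(101)
  for (i in 1:50) {
    sp <- random_conv_spec(max_extent = 8L, max_k = 4L)
    shape <- sample(3:8, 3, replace = TRUE)
    got <- tryCatch(conv_output_shape(shape, sp), error = function(e) NULL)
    want <- vapply(1:3, function(a) {
      oracle_axis_placements(shape[a], c(sp$k1, sp$k2, sp$k3)[a],
                             sp$pad, sp$stride)
    }, integer(1))
    if (any(want <= 0L)) {
      expect_error(conv_output_shape(shape, sp), "non-positive")
    } else {
      expect_equal(got, want)
    }
  }
})

test_that("output shape errors name the violating axis", {
  sp <- conv_spec(k1 = 7, pad = 0, stride = 1)
  expect_error(conv_output_shape(c(3, 10, 10), sp), "depth")
})

test_that("standard-convolution multiply count is exact", {
  sp <- conv_spec(k1 = 3, c_in = 1, c_out = 1, pad = 0, stride = 1)
  expect_identical(flops_standard(sp, c(1, 1, 1)), 27)
  # linear in output channels
  sp2 <- conv_spec(k1 = 3, c_in = 2, c_out = 4, pad = 1, stride = 1)
  sp4 <- conv_spec(k1 = 3, c_in = 2, c_out = 8, pad = 1, stride = 1)
  out <- conv_output_shape(c(5, 5, 5), sp2)
  expect_equal(flops_standard(sp4, out), 2 * flops_standard(sp2, out))
  # multiply-add convention doubles the count
  expect_equal(flops_standard(sp2, out, mult_add = TRUE),
               2 * flops_standard(sp2, out))
})

test_that("analytic FLOPs equal the instrumented naive-loop count", {
  set.seed(77)
  for (i in 1:30) {
    sp <- random_conv_spec()
    shape <- sample(3:5, 3, replace = TRUE)
    out <- tryCatch(conv_output_shape(shape, sp), error = function(e) NULL)
    if (is.null(out)) next
    expect_identical(flops_standard(sp, out), oracle_flops_standard(sp, shape))
    expect_identical(flops_dsgc(sp, out), oracle_flops_dsgc(sp, shape))
  }
})

test_that("reduction ratio closed form equals the formula quotient", {
  sp <- conv_spec(k1 = 3, c_in = 64, c_out = 64)
  expect_equal(reduction_ratio(sp), 1 / 64 + 1 / (64 * 27), tolerance = 1e-12)
  # C_out = 1: no saving, flagged
  expect_warning(r1 <- reduction_ratio(conv_spec(k1 = 3, c_in = 4, c_out = 1)),
                 "saves nothing")
  expect_equal(r1, 1 + 1 / 27)
  set.seed(5)
  for (i in 1:200) {
    sp <- random_conv_spec(max_c = 16L)
    out <- c(2L, 2L, 2L)
    quotient <- flops_dsgc(sp, out) / flops_standard(sp, out)
    r <- suppressWarnings(reduction_ratio(sp))
    expect_equal(r, quotient, tolerance = 1e-12)
  }
})

test_that("separable convolution always saves FLOPs for K=3 and C_out >= 2", {
  set.seed(6)
  for (i in 1:100) {
    c_in <- sample(1:64, 1); c_out <- sample(2:64, 1)
    sp <- conv_spec(k1 = 3, c_in = c_in, c_out = c_out)
    out <- c(4L, 4L, 4L)
    expect_lt(flops_dsgc(sp, out), flops_standard(sp, out))
  }
})

test_that("output shape is monotone in input extent and padding", {
  sp <- conv_spec(k1 = 3, pad = 1, stride = 2)
  ext <- vapply(5:12, function(n) conv_output_shape(c(n, n, n), sp)[1], integer(1))
  expect_true(all(diff(ext) >= 0))
  pads <- vapply(0:3, function(p) {
    conv_output_shape(c(7, 7, 7), conv_spec(k1 = 3, pad = p, stride = 2))[1]
  }, integer(1))
  expect_true(all(diff(pads) >= 0))
})

test_that("model complexity report is self-consistent and delegates to the formulas", {
  cfg <- tiny_config()
  rep <- model_complexity_report(cfg)
  expect_equal(sum(rep$flops), attr(rep, "total_flops"))
  expect_equal(sum(rep$params), attr(rep, "total_params"))
  expect_equal(attr(rep, "total_params"), attr(count_params(cfg), "total"))
  # fusion-path row equals the formulas: input (6,8,8) stride 2 -> (3,4,4)
  sp <- conv_spec(k1 = 3, c_in = 1, c_out = cfg$stem_channels, pad = 1, stride = 2)
  out <- conv_output_shape(c(6, 8, 8), sp)
  expect_equal(out, c(3L, 4L, 4L))
  fstd <- flops_standard(sp, out)
  # hand calculation: 27 * 1 * 4 * 48 voxels = 5184
  expect_equal(fstd, 5184)
  caeff_t1 <- rep[rep$layer == "caeff/T1WI", ]
  expect_equal(caeff_t1$flops, 5184)
  gated <- rep[rep$layer == "caeff/ADC", ]
  expect_equal(gated$flops_standard, fstd)
  expect_equal(gated$flops_dsgc, flops_dsgc(sp, out))
})
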