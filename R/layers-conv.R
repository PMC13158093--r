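# Convolutional building blocks of the fusion stem and extraction stages.
# Every block has an internal forward-with-cache (.fwd) and backward (.bwd)
# pair so the training loop can backpropagate without an autodiff framework;
# the exported functions are thin inference surfaces over the same code.

conv3d <- function(x, w, b, stride = 1L, pad = 0L, groups = 1L) {
  assert_finite(x, "convolution input")
  conv3d_fwd_cpp(x, dim(x), w, dim(w), b, as.integer(stride),
                 as.integer(pad), as.integer(groups))
}

conv3d.bwd <- function(x, w, gout, stride = 1L, pad = 0L, groups = 1L) {
  conv3d_bwd_cpp(x, dim(x), w, dim(w), gout, as.integer(stride),
                 as.integer(pad), as.integer(groups))
}

channel_scale <- function(x, s) {
  # multiply channel c of a (D,H,W,C) map by the scalar s[c]
  sweep(x, 4L, s, `*`)
}

global_avg_pool <- function(x) {
  d <- dim(x)
  colMeans(matrix(x, nrow = prod(d[1:3]), ncol = d[4]))
}

## ---- squeeze and excitation -------------------------------------------------

se_init <- function(channels, reduction) {
  if (channels %% reduction != 0L) {
    stop("SE block: channel count (", channels,
         ") not divisible by reduction (", reduction, ")", call. = FALSE)
  }
  r <- channels %/% reduction
  list(w1 = linear_init(channels, r), b1 = numeric(r),
       w2 = linear_init(r, channels), b2 = numeric(channels))
}

se.fwd <- function(x, p) {
  z <- global_avg_pool(x)
  u1 <- drop(z %*% p$w1) + p$b1
  h <- pmax(u1, 0)
  u2 <- drop(h %*% p$w2) + p$b2
  s <- sigmoid(u2)
  list(y = channel_scale(x, s),
       weights = s,
       cache = list(x = x, z = z, u1 = u1, h = h, s = s, p = p))
}

se.bwd <- function(gy, cache) {
  x <- cache$x; p <- cache$p; s <- cache$s
  d <- dim(x); nvox <- prod(d[1:3])
  gx <- channel_scale(gy, s)
  gs <- colSums(matrix(gy * x, nrow = nvox, ncol = d[4]))
  gu2 <- gs * s * (1 - s)
  gw2 <- outer(cache$h, gu2)
  gh <- drop(p$w2 %*% gu2)
  gu1 <- gh * (cache$u1 > 0)
  gw1 <- outer(cache$z, gu1)
  gz <- drop(p$w1 %*% gu1)
  # squeeze path: each voxel of channel c contributed 1/nvox to z[c]
  gx <- gx + channel_scale(array(1, dim = d), gz / nvox)
  list(gx = gx, grads = list(w1 = gw1, b1 = gu1, w2 = gw2, b2 = gu2))
}

#' Squeeze-and-excitation channel attention
#'
#' Compresses each channel of a 3D feature map to a scalar by global average
#' pooling (squeeze), passes the pooled vector through a two-layer bottleneck
#' perceptron with sigmoid output (excitation, bottleneck width
#' `channels / reduction`), and rescales every channel by its learned weight.
#'
#' @param x Numeric array `(D, H, W, C)`.
#' @param params SE weights as produced during model initialization: a list
#'   with `w1`, `b1`, `w2`, `b2`.
#' @param reduction Bottleneck reduction ratio; must divide `C`.
#' @return List with `output` (same shape as `x`) and `weights` (the per-
#'   channel excitation values, each in (0, 1)).
#' @export
se_forward <- function(x, params, reduction) {
  ch <- dim(x)[4]
  if (ch %% reduction != 0L) {
    stop("SE block: channel count (", ch, ") not divisible by reduction (",
         reduction, ")", call. = FALSE)
  }
  if (length(params$b1) != ch %/% reduction) {
    stop("SE block: parameter shapes do not match reduction ", reduction,
         call. = FALSE)
  }
  f <- se.fwd(x, params)
  list(output = f$y, weights = f$weights)
}

## ---- gating network ---------------------------------------------------------

gate_init <- function(channels) {
  list(w = linear_init(channels, channels), b = numeric(channels))
}

gate.fwd <- function(x, p) {
  z <- global_avg_pool(x)
  g <- sigmoid(drop(z %*% p$w) + p$b)
  list(g = g, cache = list(z = z, g = g, p = p, dims = dim(x)))
}

gate.bwd <- function(gg, cache) {
  gu <- gg * cache$g * (1 - cache$g)
  gw <- outer(cache$z, gu)
  gz <- drop(cache$p$w %*% gu)
  d <- cache$dims; nvox <- prod(d[1:3])
  gx <- channel_scale(array(1, dim = d), gz / nvox)
  list(gx = gx, grads = list(w = gw, b = gu))
}

#' Gating network: per-channel routing weights
#'
#' Pools each channel globally, applies a learned affine map over the pooled
#' vector and a sigmoid, yielding one routing weight per channel in (0, 1).
#' In the fusion stem, a channel's weight blends its standard-convolution path
#' (weight g) with its depthwise separable group convolution path (weight
#' 1 - g); in the extraction stages the weights recalibrate the feature map
#' multiplicatively.
#'
#' @param x Numeric array `(D, H, W, C)`; must be free of NaN/Inf.
#' @param params List with affine weights `w` (C x C) and bias `b` (length C).
#' @return Numeric vector of `C` gate values in (0, 1).
#' @export
gate_forward <- function(x, params) {
  assert_finite(x, "gating-network input")
  gate.fwd(x, params)$g
}

## ---- depthwise separable group convolution ---------------------------------

dsgc_init <- function(c_in, c_out, k = 3L) {
  g <- gcd_int(c_in, c_out)
  list(dw = list(w = kaiming_conv(c(k, k, k, 1L, c_in)), b = numeric(c_in)),
       pw = list(w = kaiming_conv(c(1L, 1L, 1L, c_in %/% g, c_out)),
                 b = numeric(c_out)))
}

# pointwise group count, recovered from the weight shapes
dsgc_groups <- function(p, c_in) c_in %/% dim(p$pw$w)[4]

dsgc.fwd <- function(x, p, stride = 1L, pad = 1L) {
  c_in <- dim(x)[4]
  mid <- conv3d(x, p$dw$w, p$dw$b, stride = stride, pad = pad, groups = c_in)
  y <- conv3d(mid, p$pw$w, p$pw$b, stride = 1L, pad = 0L,
              groups = dsgc_groups(p, c_in))
  list(y = y, cache = list(x = x, mid = mid, p = p, stride = stride, pad = pad))
}

dsgc.bwd <- function(gy, cache) {
  p <- cache$p
  c_in <- dim(cache$x)[4]
  bp <- conv3d.bwd(cache$mid, p$pw$w, gy, stride = 1L, pad = 0L,
                   groups = dsgc_groups(p, c_in))
  bd <- conv3d.bwd(cache$x, p$dw$w, bp$gx, stride = cache$stride,
                   pad = cache$pad, groups = c_in)
  list(gx = bd$gx,
       grads = list(dw = list(w = bd$gw, b = bd$gb),
                    pw = list(w = bp$gw, b = bp$gb)))
}

#' Depthwise separable group convolution
#'
#' Two-stage efficient convolution: a per-channel (depthwise) spatial
#' convolution, followed by a 1x1x1 pointwise convolution whose channels are
#' grouped by `gcd(C_in, C_out)`. Spatial output extents follow the standard
#' sliding-window rule `floor((in + 2P - K) / S) + 1`.
#'
#' @param x Numeric array `(D, H, W, C_in)`.
#' @param params Parameter list from model initialization (`dw`, `pw`,
#'   `groups`).
#' @param stride,pad Stride and symmetric padding of the depthwise stage.
#' @return Numeric array `(D', H', W', C_out)`.
#' @export
dsgc_forward <- function(x, params, stride = 1L, pad = 1L) {
  dsgc.fwd(x, params, stride = stride, pad = pad)$y
}

## ---- multi-scale feature extraction stage ----------------------------------

msfe_init <- function(c_in, c_out, k = 3L) {
  list(gn = gate_init(c_in), dsgc = dsgc_init(c_in, c_out, k))
}

msfe.fwd <- function(x, p, stride = 1L, pad = 1L) {
  gf <- gate.fwd(x, p$gn)
  xm <- channel_scale(x, gf$g)
  df <- dsgc.fwd(xm, p$dsgc, stride = stride, pad = pad)
  list(y = df$y, g = gf$g,
       cache = list(x = x, gf = gf, df = df))
}

msfe.bwd <- function(gy, cache) {
  db <- dsgc.bwd(gy, cache$df$cache)
  g <- cache$gf$g
  gxm <- db$gx
  gx <- channel_scale(gxm, g)
  d <- dim(cache$x); nvox <- prod(d[1:3])
  gg <- colSums(matrix(gxm * cache$x, nrow = nvox, ncol = d[4]))
  gb <- gate.bwd(gg, cache$gf$cache)
  list(gx = gx + gb$gx,
       grads = list(gn = gb$grads, dsgc = db$grads))
}

#' Multi-scale feature extraction stage
#'
#' Recalibrates the input feature map by element-wise multiplication with the
#' gating network's per-channel weights, then applies the depthwise separable
#' group convolution.
#'
#' @inheritParams dsgc_forward
#' @param params Stage parameters (`gn` gating network, `dsgc` convolution).
#' @return List with `output` and `gates` (the modulation weights).
#' @export
msfe_forward <- function(x, params, stride = 1L, pad = 1L) {
  f <- msfe.fwd(x, params, stride = stride, pad = pad)
  list(output = f$y, gates = f$g)
}

## ---- channel-attention enhanced feature fusion ------------------------------

# one path per MRI sequence; path 2 (T1WI) is standard conv + SE, the others
# blend standard conv (weight g) with DSGC (weight 1 - g)
caeff_init <- function(cfg) {
  k <- 3L
  paths <- vector("list", 5L)
  for (c in 1:5) {
    path <- list(conv = list(w = kaiming_conv(c(k, k, k, 1L, cfg$stem_channels)),
                             b = numeric(cfg$stem_channels)))
    if (c == 2L) {
      path$se <- se_init(cfg$stem_channels, cfg$se_reduction)
    } else {
      path$gate <- gate_init(1L)
      path$dsgc <- dsgc_init(1L, cfg$stem_channels, k)
    }
    paths[[c]] <- path
  }
  names(paths) <- cvit_sequences()
  paths
}

caeff.fwd <- function(x, p, stride = 2L, hard_gates = FALSE, threshold = 0.5) {
  d <- dim(x)
  if (d[4] != 5L) stop("fusion stem expects exactly 5 input channels, got ", d[4],
                       call. = FALSE)
  outs <- vector("list", 5L)
  caches <- vector("list", 5L)
  gates <- rep(NA_real_, 5L)
  se_w <- NULL
  for (c in 1:5) {
    xc <- array(x[, , , c], dim = c(d[1:3], 1L))
    pc <- p[[c]]
    conv_out <- conv3d(xc, pc$conv$w, pc$conv$b, stride = stride, pad = 1L)
    if (c == 2L) {
      sf <- se.fwd(conv_out, pc$se)
      outs[[c]] <- sf$y
      se_w <- sf$weights
      caches[[c]] <- list(xc = xc, pc = pc, se = sf$cache)
    } else {
      gf <- gate.fwd(xc, pc$gate)
      g <- gf$g
      if (hard_gates) g <- as.numeric(g >= threshold)
      df <- dsgc.fwd(xc, pc$dsgc, stride = stride, pad = 1L)
      outs[[c]] <- g * conv_out + (1 - g) * df$y
      gates[c] <- g
      caches[[c]] <- list(xc = xc, pc = pc, conv_out = conv_out, gf = gf,
                          df = df, g_used = g, hard = hard_gates)
    }
  }
  y <- array(0, dim = c(dim(outs[[1]])[1:3], 5L * dim(outs[[1]])[4]))
  cs <- dim(outs[[1]])[4]
  for (c in 1:5) y[, , , ((c - 1L) * cs + 1L):(c * cs)] <- outs[[c]]
  list(y = y,
       gates = stats::setNames(gates[-2L], cvit_sequences()[-2L]),
       se_weights = se_w,
       cache = list(caches = caches, stride = stride, cs = cs, xdim = d))
}

caeff.bwd <- function(gy, cache) {
  cs <- cache$cs
  stride <- cache$stride
  d <- cache$xdim
  gx <- array(0, dim = d)
  grads <- vector("list", 5L)
  names(grads) <- cvit_sequences()
  for (c in 1:5) {
    cc <- cache$caches[[c]]
    pc <- cc$pc
    gyc <- array(gy[, , , ((c - 1L) * cs + 1L):(c * cs)],
                 dim = c(dim(gy)[1:3], cs))
    if (c == 2L) {
      sb <- se.bwd(gyc, cc$se)
      cb <- conv3d.bwd(cc$xc, pc$conv$w, sb$gx, stride = stride, pad = 1L)
      gx[, , , c] <- cb$gx
      grads[[c]] <- list(conv = list(w = cb$gw, b = cb$gb), se = sb$grads)
    } else {
      g <- cc$g_used
      # blend: y = g * conv + (1 - g) * dsgc
      cb <- conv3d.bwd(cc$xc, pc$conv$w, g * gyc, stride = stride, pad = 1L)
      db <- dsgc.bwd((1 - g) * gyc, cc$df$cache)
      gxc <- cb$gx + db$gx
      gate_grads <- list(w = cc$gf$cache$p$w * 0, b = 0 * cc$gf$cache$p$b)
      if (!cc$hard) {
        gg <- sum(gyc * (cc$conv_out - cc$df$y))
        gb <- gate.bwd(gg, cc$gf$cache)
        gxc <- gxc + gb$gx
        gate_grads <- gb$grads
      }
      gx[, , , c] <- gxc
      grads[[c]] <- list(conv = list(w = cb$gw, b = cb$gb),
                         gate = gate_grads, dsgc = db$grads)
    }
  }
  list(gx = gx, grads = grads)
}

#' Channel-attention enhanced feature fusion stem
#'
#' Fuses the five MRI sequences: each sequence enters its own convolutional
#' path. The T1WI path (channel 2 of the canonical order) is a standard
#' convolution followed by squeeze-and-excitation channel attention; every
#' other path is routed by a gating network between a standard convolution
#' (weight g) and a depthwise separable group convolution (weight 1 - g) as a
#' convex blend. Per-path outputs are concatenated along the channel axis.
#'
#' @param x Numeric array `(D, H, W, 5)` in canonical sequence order
#'   (CE-T1WI, T1WI, T2WI, FLAIR, ADC).
#' @param params Stem parameters from model initialization (one sublist per
#'   sequence).
#' @param stride Spatial stride of all paths.
#' @param hard_gates If `TRUE`, threshold the gates at `threshold` so each
#'   routed channel uses exactly one path (inference-time hard routing).
#' @param threshold Hard-routing threshold.
#' @return List with `output` (fused map, `5 * stem_channels` channels),
#'   `gates` (named routing weights of the four gated sequences) and
#'   `se_weights` (excitation weights of the T1WI path).
#' @export
caeff_forward <- function(x, params, stride = 2L, hard_gates = FALSE,
                          threshold = 0.5) {
  f <- caeff.fwd(x, params, stride = stride, hard_gates = hard_gates,
                 threshold = threshold)
  list(output = f$y, gates = f$gates, se_weights = f$se_weights)
}

gcd_int <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}
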