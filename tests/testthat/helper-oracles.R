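# Independent oracles used across the suite. These are deliberately naive
# (scalar loops, exhaustive enumeration) and share no code with the package
# internals they check.

# naive grouped 3D convolution: scalar loops over every output element
oracle_conv3d <- function(x, w, b, stride = 1L, pad = 0L, groups = 1L) {
  d <- dim(x); k <- dim(w)
  D <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  K1 <- k[1]; K2 <- k[2]; K3 <- k[3]; Cg <- k[4]; Co <- k[5]
  cog <- Co / groups
  Do <- (D + 2 * pad - K1) %/% stride + 1L
  Ho <- (H + 2 * pad - K2) %/% stride + 1L
  Wo <- (W + 2 * pad - K3) %/% stride + 1L
  out <- array(0, c(Do, Ho, Wo, Co))
  for (co in seq_len(Co)) {
    g <- (co - 1) %/% cog
    for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) for (dd in seq_len(Do)) {
      acc <- b[co]
      for (cg in seq_len(Cg)) {
        ci <- g * Cg + cg
        for (k3 in seq_len(K3)) for (k2 in seq_len(K2)) for (k1 in seq_len(K1)) {
          di <- (dd - 1) * stride - pad + k1
          hi <- (ho - 1) * stride - pad + k2
          wi <- (wo - 1) * stride - pad + k3
          if (di >= 1 && di <= D && hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
            acc <- acc + x[di, hi, wi, ci] * w[k1, k2, k3, cg, co]
          }
        }
      }
      out[dd, ho, wo, co] <- acc
    }
  }
  out
}

# count of valid sliding-window placements along one axis, enumerated
oracle_axis_placements <- function(extent, k, pad, stride) {
  n <- 0L
  start <- 1L
  padded <- extent + 2L * pad
  while (start + k - 1L <= padded) {
    n <- n + 1L
    start <- start + stride
  }
  n
}

# multiply count of the naive standard convolution: literal loop with counter
oracle_flops_standard <- function(spec, in_shape) {
  k <- c(spec$k1, spec$k2, spec$k3)
  outs <- vapply(1:3, function(a) {
    oracle_axis_placements(in_shape[a], k[a], spec$pad, spec$stride)
  }, integer(1))
  n <- 0
  for (co in seq_len(spec$c_out)) for (v in seq_len(prod(outs))) {
    for (ci in seq_len(spec$c_in)) for (t in seq_len(prod(k))) n <- n + 1
  }
  n
}

# multiply count of the two-stage separable grouped convolution
oracle_flops_dsgc <- function(spec, in_shape) {
  k <- c(spec$k1, spec$k2, spec$k3)
  outs <- vapply(1:3, function(a) {
    oracle_axis_placements(in_shape[a], k[a], spec$pad, spec$stride)
  }, integer(1))
  g <- 1L
  for (cand in seq_len(min(spec$c_in, spec$c_out))) {
    if (spec$c_in %% cand == 0L && spec$c_out %% cand == 0L) g <- cand
  }
  n <- 0
  # stage A: depthwise, one kernel per input channel
  for (ci in seq_len(spec$c_in)) for (v in seq_len(prod(outs))) {
    for (t in seq_len(prod(k))) n <- n + 1
  }
  # stage B: pointwise grouped 1x1x1
  for (co in seq_len(spec$c_out)) for (v in seq_len(prod(outs))) {
    for (cg in seq_len(spec$c_in %/% g)) n <- n + 1
  }
  n
}

# exhaustive pairwise AUC: wins + half ties over all positive-negative pairs
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# scalar-loop SE block: pool -> perceptron -> sigmoid -> scale
oracle_se <- function(x, p) {
  d <- dim(x); C <- d[4]
  z <- numeric(C)
  for (c in seq_len(C)) {
    s <- 0
    for (w in seq_len(d[3])) for (h in seq_len(d[2])) for (dd in seq_len(d[1])) {
      s <- s + x[dd, h, w, c]
    }
    z[c] <- s / (d[1] * d[2] * d[3])
  }
  r <- length(p$b1)
  h1 <- numeric(r)
  for (j in seq_len(r)) {
    acc <- p$b1[j]
    for (c in seq_len(C)) acc <- acc + z[c] * p$w1[c, j]
    h1[j] <- max(acc, 0)
  }
  s <- numeric(C)
  for (c in seq_len(C)) {
    acc <- p$b2[c]
    for (j in seq_len(r)) acc <- acc + h1[j] * p$w2[j, c]
    s[c] <- 1 / (1 + exp(-acc))
  }
  out <- x
  for (c in seq_len(C)) out[, , , c] <- x[, , , c] * s[c]
  list(y = out, weights = s)
}

# naive per-head attention with explicit Q/K/V slicing and softmax
oracle_mhsa <- function(tok, p, num_heads) {
  e <- ncol(tok); n <- nrow(tok); hd <- e / num_heads
  q <- tok %*% p$wq + matrix(p$bq, n, e, byrow = TRUE)
  k <- tok %*% p$wk + matrix(p$bk, n, e, byrow = TRUE)
  v <- tok %*% p$wv + matrix(p$bv, n, e, byrow = TRUE)
  o <- matrix(0, n, e)
  for (h in seq_len(num_heads)) {
    idx <- ((h - 1) * hd + 1):(h * hd)
    for (i in seq_len(n)) {
      sc <- numeric(n)
      for (j in seq_len(n)) sc[j] <- sum(q[i, idx] * k[j, idx]) / sqrt(hd)
      a <- exp(sc - max(sc)); a <- a / sum(a)
      for (j in seq_len(n)) o[i, idx] <- o[i, idx] + a[j] * v[j, idx]
    }
  }
  o %*% p$wo + matrix(p$bo, n, e, byrow = TRUE)
}

random_conv_spec <- function(max_extent = 5L, max_k = 3L, max_c = 3L) {
  conv_spec(k1 = sample(max_k, 1), k2 = sample(max_k, 1), k3 = sample(max_k, 1),
            c_in = sample(max_c, 1), c_out = sample(max_c, 1),
            pad = sample(0:1, 1), stride = sample(1:2, 1))
}

tiny_config <- function(...) {
  cvit_config("desk", input_shape = c(6L, 8L, 8L), stem_channels = 4L,
              msfe_channels = c(6L, 8L), embed_dim = 12L, depth = 2L,
              num_heads = 3L, mlp_ratio = 2, se_reduction = 2L, ...)
}

tiny_phantom_batch <- function(n, seed = 1L, grid = c(6L, 8L, 8L)) {
  generate_phantom_dataset(n, grid = grid, seed = seed)
}
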