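# Low-level numeric helpers shared by the network layers. Feature maps are
# numeric arrays with dim (D, H, W, C); token matrices are (tokens, embed).

sigmoid <- function(x) 1 / (1 + exp(-x))

# exact GELU, x * Phi(x), and its derivative
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

assert_finite <- function(x, what) {
  if (anyNA(x) || any(is.infinite(x))) {
    stop("non-finite values in ", what, call. = FALSE)
  }
  invisible(x)
}

# truncated normal at +/- 2 sigma, rejection sampling (draws through the
# session RNG so a single set.seed governs all initialization)
rtruncnorm2 <- function(n, sd = 0.02) {
  out <- stats::rnorm(n, 0, sd)
  bad <- which(abs(out) > 2 * sd)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[abs(out[bad]) > 2 * sd]
  }
  out
}

# Kaiming-normal for convolution kernels: sd = sqrt(2 / fan_in)
kaiming_conv <- function(kdim) {
  fan_in <- prod(kdim[1:4])
  array(stats::rnorm(prod(kdim), 0, sqrt(2 / fan_in)), dim = kdim)
}

linear_init <- function(n_in, n_out, sd = 0.02) {
  matrix(rtruncnorm2(n_in * n_out, sd), nrow = n_in, ncol = n_out)
}

# layer norm over the last (feature) axis of a token matrix, with cache
layer_norm_fwd <- function(x, gamma, beta, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2L, gamma, `*`)
  y <- sweep(y, 2L, beta, `+`)
  list(y = y, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

layer_norm_bwd <- function(gy, cache) {
  xhat <- cache$xhat; inv <- cache$inv; gamma <- cache$gamma
  n <- ncol(xhat)
  gxhat <- sweep(gy, 2L, gamma, `*`)
  # standard layer-norm backward over the feature axis
  gx <- inv * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
  list(gx = gx,
       ggamma = colSums(gy * xhat),
       gbeta = colSums(gy))
}

# elementwise binary walk over two parameter trees of identical shape
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(a[[i]], f)
    out
  } else {
    f(a)
  }
}

tree_zero_like <- function(a) tree_map(a, function(x) x * 0)

tree_n_params <- function(a) {
  if (is.list(a)) sum(vapply(a, tree_n_params, numeric(1))) else length(a)
}
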