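# Transformer encoder over tokens derived from the CNN feature map.
# Token matrices are (tokens, embed); token 1 is the CLS token.

tokenize_init <- function(c_in, n_tokens, embed_dim) {
  list(proj = linear_init(c_in, embed_dim),
       bproj = numeric(embed_dim),
       cls = rtruncnorm2(embed_dim),
       pos = matrix(rtruncnorm2((n_tokens + 1L) * embed_dim),
                    nrow = n_tokens + 1L, ncol = embed_dim))
}

tokenize.fwd <- function(x, p) {
  d <- dim(x)
  v <- prod(d[1:3])
  if (nrow(p$pos) != v + 1L) {
    stop("tokenizer configured for ", nrow(p$pos) - 1L,
         " spatial positions but feature map has ", v, call. = FALSE)
  }
  xm <- matrix(x, nrow = v, ncol = d[4])
  tok <- xm %*% p$proj
  tok <- sweep(tok, 2L, p$bproj, `+`)
  tok <- rbind(p$cls, tok, deparse.level = 0)
  tok <- tok + p$pos
  list(y = tok, cache = list(xm = xm, p = p, xdim = d))
}

tokenize.bwd <- function(gy, cache) {
  p <- cache$p
  gpos <- gy
  gcls <- gy[1L, ]
  gtok <- gy[-1L, , drop = FALSE]
  gproj <- crossprod(cache$xm, gtok)
  gbproj <- colSums(gtok)
  gx <- array(gtok %*% t(p$proj), dim = cache$xdim)
  list(gx = gx,
       grads = list(proj = gproj, bproj = gbproj, cls = gcls, pos = gpos))
}

#' Tokenize a 3D feature map for the transformer encoder
#'
#' Each spatial position of the feature map becomes one token via a linear
#' projection of its channel vector to the embedding width; a learnable CLS
#' token is prepended and learnable positional embeddings are added. Spatial
#' positions map to token rows in column-major order (depth fastest), so the
#' token index of voxel (d, h, w) is `1 + d + D*(h + H*w)` plus one for CLS.
#'
#' @param x Numeric array `(D, H, W, C)` with at least one voxel.
#' @param params Tokenizer parameters (`proj`, `bproj`, `cls`, `pos`).
#' @return Matrix `(D*H*W + 1, embed_dim)`; row 1 is the CLS token.
#' @export
tokenize <- function(x, params) {
  if (ncol(params$proj) != length(params$cls)) {
    stop("tokenizer embed_dim mismatch between projection and CLS token",
         call. = FALSE)
  }
  tokenize.fwd(x, params)$y
}

## ---- multi-head self-attention ---------------------------------------------

mhsa_init <- function(embed_dim) {
  list(wq = linear_init(embed_dim, embed_dim), bq = numeric(embed_dim),
       wk = linear_init(embed_dim, embed_dim), bk = numeric(embed_dim),
       wv = linear_init(embed_dim, embed_dim), bv = numeric(embed_dim),
       wo = linear_init(embed_dim, embed_dim), bo = numeric(embed_dim))
}

mhsa.fwd <- function(tok, p, num_heads) {
  e <- ncol(tok)
  if (e %% num_heads != 0L) {
    stop("embedding width (", e, ") not divisible by head count (",
         num_heads, ")", call. = FALSE)
  }
  hd <- e %/% num_heads
  n <- nrow(tok)
  q <- sweep(tok %*% p$wq, 2L, p$bq, `+`)
  k <- sweep(tok %*% p$wk, 2L, p$bk, `+`)
  v <- sweep(tok %*% p$wv, 2L, p$bv, `+`)
  attn <- array(0, dim = c(n, n, num_heads))
  heads <- vector("list", num_heads)
  o <- matrix(0, n, e)
  for (h in seq_len(num_heads)) {
    idx <- ((h - 1L) * hd + 1L):(h * hd)
    s <- tcrossprod(q[, idx, drop = FALSE], k[, idx, drop = FALSE]) / sqrt(hd)
    if (anyNA(s)) stop("NaN entered the attention softmax", call. = FALSE)
    a <- softmax_rows(s)
    attn[, , h] <- a
    o[, idx] <- a %*% v[, idx, drop = FALSE]
    heads[[h]] <- list(a = a, idx = idx)
  }
  y <- sweep(o %*% p$wo, 2L, p$bo, `+`)
  list(y = y, attn = attn,
       cache = list(tok = tok, q = q, k = k, v = v, o = o, heads = heads,
                    p = p, hd = hd))
}

mhsa.bwd <- function(gy, cache) {
  p <- cache$p; hd <- cache$hd
  go <- gy %*% t(p$wo)
  gwo <- crossprod(cache$o, gy)
  gbo <- colSums(gy)
  gq <- gk <- gv <- matrix(0, nrow(go), ncol(go))
  for (hh in cache$heads) {
    idx <- hh$idx
    a <- hh$a
    goh <- go[, idx, drop = FALSE]
    ga <- tcrossprod(goh, cache$v[, idx, drop = FALSE])
    gv[, idx] <- crossprod(a, goh)
    # softmax backward, row-wise
    gs <- a * (ga - rowSums(ga * a))
    gs <- gs / sqrt(hd)
    gq[, idx] <- gs %*% cache$k[, idx, drop = FALSE]
    gk[, idx] <- crossprod(gs, cache$q[, idx, drop = FALSE])
  }
  gtok <- gq %*% t(p$wq) + gk %*% t(p$wk) + gv %*% t(p$wv)
  list(gx = gtok,
       grads = list(wq = crossprod(cache$tok, gq), bq = colSums(gq),
                    wk = crossprod(cache$tok, gk), bk = colSums(gk),
                    wv = crossprod(cache$tok, gv), bv = colSums(gv),
                    wo = gwo, bo = gbo))
}

#' Multi-head self-attention
#'
#' Standard scaled dot-product attention: the token matrix is projected to
#' queries, keys and values, split into `num_heads` subspaces of width
#' `embed_dim / num_heads`, attended per head with softmax over
#' `Q K' / sqrt(head_dim)`, concatenated and passed through an output
#' projection. Each attention row is a probability distribution (sums to 1).
#'
#' @param tokens Matrix `(tokens, embed_dim)`.
#' @param params Attention parameters (`wq`, `bq`, `wk`, `bk`, `wv`, `bv`,
#'   `wo`, `bo`).
#' @param num_heads Number of attention heads; must divide the embedding
#'   width.
#' @return List with `output` (same shape as `tokens`) and `attention`, an
#'   array `(tokens, tokens, heads)` of attention weights.
#' @export
mhsa_forward <- function(tokens, params, num_heads) {
  f <- mhsa.fwd(tokens, params, num_heads)
  list(output = f$y, attention = f$attn)
}

## ---- encoder block (pre-norm MHSA + MLP) -----------------------------------

encoder_block_init <- function(embed_dim, num_heads, mlp_ratio) {
  hidden <- as.integer(round(mlp_ratio * embed_dim))
  list(ln1 = list(gamma = rep(1, embed_dim), beta = numeric(embed_dim)),
       attn = mhsa_init(embed_dim),
       ln2 = list(gamma = rep(1, embed_dim), beta = numeric(embed_dim)),
       mlp = list(w1 = linear_init(embed_dim, hidden), b1 = numeric(hidden),
                  w2 = linear_init(hidden, embed_dim), b2 = numeric(embed_dim)))
}

mlp.fwd <- function(x, p) {
  u <- sweep(x %*% p$w1, 2L, p$b1, `+`)
  h <- gelu(u)
  y <- sweep(h %*% p$w2, 2L, p$b2, `+`)
  list(y = y, cache = list(x = x, u = u, h = h, p = p))
}

mlp.bwd <- function(gy, cache) {
  p <- cache$p
  gh <- gy %*% t(p$w2)
  gu <- gh * gelu_grad(cache$u)
  gx <- gu %*% t(p$w1)
  list(gx = gx,
       grads = list(w1 = crossprod(cache$x, gu), b1 = colSums(gu),
                    w2 = crossprod(cache$h, gy), b2 = colSums(gy)))
}

encoder_block.fwd <- function(tok, p, num_heads) {
  l1 <- layer_norm_fwd(tok, p$ln1$gamma, p$ln1$beta)
  at <- mhsa.fwd(l1$y, p$attn, num_heads)
  t1 <- tok + at$y
  l2 <- layer_norm_fwd(t1, p$ln2$gamma, p$ln2$beta)
  ml <- mlp.fwd(l2$y, p$mlp)
  y <- t1 + ml$y
  list(y = y, attn = at$attn,
       cache = list(l1 = l1, at = at, l2 = l2, ml = ml))
}

encoder_block.bwd <- function(gy, cache) {
  mb <- mlp.bwd(gy, cache$ml$cache)
  lb2 <- layer_norm_bwd(mb$gx, cache$l2$cache)
  gt1 <- gy + lb2$gx
  ab <- mhsa.bwd(gt1, cache$at$cache)
  lb1 <- layer_norm_bwd(ab$gx, cache$l1$cache)
  gx <- gt1 + lb1$gx
  list(gx = gx,
       grads = list(ln1 = list(gamma = lb1$ggamma, beta = lb1$gbeta),
                    attn = ab$grads,
                    ln2 = list(gamma = lb2$ggamma, beta = lb2$gbeta),
                    mlp = mb$grads))
}

#' Transformer encoder block
#'
#' One encoder layer: pre-norm multi-head self-attention with a residual
#' connection, then a pre-norm feed-forward network (hidden width
#' `mlp_ratio * embed_dim`, GELU) with a residual connection. Token count and
#' embedding width are preserved.
#'
#' @param tokens Matrix `(tokens, embed_dim)`.
#' @param params Block parameters (`ln1`, `attn`, `ln2`, `mlp`).
#' @param num_heads Number of attention heads.
#' @return List with `output` and `attention` as in [mhsa_forward()].
#' @export
encoder_block_forward <- function(tokens, params, num_heads) {
  f <- encoder_block.fwd(tokens, params, num_heads)
  list(output = f$y, attention = f$attn)
}

## ---- classification head ----------------------------------------------------

head_init <- function(embed_dim) {
  half <- max(1L, embed_dim %/% 2L)
  list(w1 = linear_init(embed_dim, embed_dim), b1 = numeric(embed_dim),
       ln = list(gamma = rep(1, embed_dim), beta = numeric(embed_dim)),
       w2 = linear_init(embed_dim, half), b2 = numeric(half),
       w3 = linear_init(half, 1L), b3 = 0)
}

clshead.fwd <- function(cls, p) {
  u1 <- drop(cls %*% p$w1) + p$b1
  l <- layer_norm_fwd(matrix(u1, nrow = 1L), p$ln$gamma, p$ln$beta)
  u2 <- drop(l$y %*% p$w2) + p$b2
  logit <- drop(u2 %*% p$w3) + p$b3
  list(y = logit, cache = list(cls = cls, u1 = u1, l = l, u2 = u2, p = p))
}

clshead.bwd <- function(glogit, cache) {
  p <- cache$p
  gu2 <- glogit * drop(p$w3)
  gln <- matrix(gu2, nrow = 1L) %*% t(p$w2)
  lb <- layer_norm_bwd(gln, cache$l$cache)
  gu1 <- drop(lb$gx)
  gcls <- drop(matrix(gu1, nrow = 1L) %*% t(p$w1))
  list(gx = gcls,
       grads = list(w1 = outer(cache$cls, gu1), b1 = gu1,
                    ln = list(gamma = lb$ggamma, beta = lb$gbeta),
                    w2 = outer(drop(cache$l$y), gu2),
                    b2 = gu2,
                    w3 = matrix(cache$u2 * glogit, ncol = 1L), b3 = glogit))
}
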