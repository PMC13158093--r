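#' Bundle volumes into a batch
#'
#' Light container for 5-channel volumes plus optional masks and binary
#' labels. Volumes are `(D, H, W, 5)` arrays in canonical sequence order.
#'
#' @param volumes List of numeric arrays `(D, H, W, 5)`.
#' @param labels Optional binary vector (1 = high grade), one per volume.
#' @param masks Optional list of `(D, H, W)` binary arrays.
#' @return A `cvit_batch` list.
#' @export
volume_batch <- function(volumes, labels = NULL, masks = NULL) {
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (length(dim(v)) != 4L || dim(v)[4] != 5L) {
      stop("volume ", i, ": expected a (D, H, W, 5) array", call. = FALSE)
    }
    assert_finite(v, paste0("volume ", i))
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(volumes), all(labels %in% c(0, 1)))
  }
  if (!is.null(masks)) {
    stopifnot(length(masks) == length(volumes))
    for (m in masks) stopifnot(all(m %in% c(0, 1)))
  }
  structure(list(volumes = volumes, labels = labels, masks = masks),
            class = "cvit_batch")
}

#' @export
print.cvit_batch <- function(x, ...) {
  d <- dim(x$volumes[[1]])
  cat("<cvit_batch: ", length(x$volumes), " volumes of ",
      paste(d[1:3], collapse = " x "), ", 5 sequences",
      if (!is.null(x$labels)) paste0(", ", sum(x$labels), " high-grade"), ">\n",
      sep = "")
  invisible(x)
}

# spatial extent after one convolution stage (K = 3, pad = 1, given stride)
stage_extent <- function(extent, stride) {
  (extent + 2L - 3L) %/% stride + 1L
}

# all intermediate feature-map shapes of a configuration
cvit_shapes <- function(cfg) {
  d <- cfg$input_shape
  shapes <- list(input = c(d, 5L))
  d <- vapply(d, stage_extent, integer(1), stride = cfg$caeff_stride)
  shapes$caeff <- c(d, 5L * cfg$stem_channels)
  for (i in seq_along(cfg$msfe_channels)) {
    d <- vapply(d, stage_extent, integer(1), stride = cfg$msfe_stride)
    shapes[[paste0("msfe", i)]] <- c(d, cfg$msfe_channels[i])
  }
  shapes$tokens <- c(prod(d) + 1L, cfg$embed_dim)
  shapes
}

#' Instantiate a 3D C-Vit model
#'
#' Allocates and initializes all trainable parameters of the network
#' described by a [cvit_config()]: Kaiming-normal convolution kernels,
#' truncated-normal (sd 0.02) projections, unit layer-norm gains. All random
#' draws go through a single seed.
#'
#' @param config A [cvit_config()].
#' @param seed Integer seed governing every initialization draw.
#' @return A `cvit_model` list with elements `config` and `params`.
#' @export
cvit_model <- function(config, seed = 1L) {
  validate_cvit_config(config)
  set.seed(seed)
  shapes <- cvit_shapes(config)
  n_stages <- length(config$msfe_channels)
  msfe <- vector("list", n_stages)
  c_prev <- 5L * config$stem_channels
  for (i in seq_len(n_stages)) {
    msfe[[i]] <- msfe_init(c_prev, config$msfe_channels[i])
    c_prev <- config$msfe_channels[i]
  }
  n_tokens <- shapes$tokens[1] - 1L
  params <- list(
    caeff = caeff_init(config),
    msfe = msfe,
    tokenizer = tokenize_init(c_prev, n_tokens, config$embed_dim),
    blocks = lapply(seq_len(config$depth), function(i) {
      encoder_block_init(config$embed_dim, config$num_heads, config$mlp_ratio)
    }),
    head = head_init(config$embed_dim)
  )
  structure(list(config = config, params = params, seed = seed),
            class = "cvit_model")
}

#' @export
print.cvit_model <- function(x, ...) {
  cat("<cvit_model>\n")
  print(x$config)
  cat("  trainable parameters: ",
      format(tree_n_params(x$params), big.mark = ","), "\n", sep = "")
  invisible(x)
}

# single-sample forward with caches (training) or bundle (inference)
model.fwd_sample <- function(model, x, keep_cache = FALSE, hard_gates = FALSE) {
  cfg <- model$config
  p <- model$params
  cf <- caeff.fwd(x, p$caeff, stride = cfg$caeff_stride,
                  hard_gates = hard_gates, threshold = cfg$gate_threshold)
  feat <- cf$y
  mcaches <- vector("list", length(p$msfe))
  mgates <- vector("list", length(p$msfe))
  for (i in seq_along(p$msfe)) {
    mf <- msfe.fwd(feat, p$msfe[[i]], stride = cfg$msfe_stride, pad = 1L)
    feat <- mf$y
    mgates[[i]] <- mf$g
    mcaches[[i]] <- mf
  }
  tk <- tokenize.fwd(feat, p$tokenizer)
  tok <- tk$y
  bcaches <- vector("list", length(p$blocks))
  attn <- vector("list", length(p$blocks))
  for (i in seq_along(p$blocks)) {
    bf <- encoder_block.fwd(tok, p$blocks[[i]], cfg$num_heads)
    tok <- bf$y
    attn[[i]] <- bf$attn
    bcaches[[i]] <- bf
  }
  cls <- tok[1L, ]
  hf <- clshead.fwd(cls, p$head)
  out <- list(
    logit = hf$y,
    bundle = list(se_weights = cf$se_weights, gates = cf$gates,
                  msfe_gates = mgates, attention = attn, cls = cls)
  )
  if (keep_cache) {
    out$cache <- list(cf = cf, mcaches = mcaches, tk = tk, bcaches = bcaches,
                      hf = hf, n_tokens = nrow(tok))
  }
  out
}

model.bwd_sample <- function(model, glogit, cache) {
  p <- model$params
  hb <- clshead.bwd(glogit, cache$hf$cache)
  gtok <- matrix(0, cache$n_tokens, model$config$embed_dim)
  gtok[1L, ] <- hb$gx
  gblocks <- vector("list", length(p$blocks))
  for (i in rev(seq_along(p$blocks))) {
    bb <- encoder_block.bwd(gtok, cache$bcaches[[i]]$cache)
    gtok <- bb$gx
    gblocks[[i]] <- bb$grads
  }
  tb <- tokenize.bwd(gtok, cache$tk$cache)
  gfeat <- tb$gx
  gmsfe <- vector("list", length(p$msfe))
  for (i in rev(seq_along(p$msfe))) {
    mb <- msfe.bwd(gfeat, cache$mcaches[[i]]$cache)
    gfeat <- mb$gx
    gmsfe[[i]] <- mb$grads
  }
  cb <- caeff.bwd(gfeat, cache$cf$cache)
  list(gx = cb$gx,
       grads = list(caeff = cb$grads, msfe = gmsfe, tokenizer = tb$grads,
                    blocks = gblocks, head = hb$grads))
}

#' Forward pass of the 3D C-Vit network
#'
#' Runs the full pipeline — fusion stem, multi-scale extraction stages,
#' tokenization, transformer encoder, classification head — and returns one
#' logit per volume together with the interpretability bundle (SE weights,
#' routing gates, per-layer attention maps, CLS features).
#'
#' @param model A [cvit_model()].
#' @param batch A [volume_batch()] (or bare list of `(D, H, W, 5)` arrays).
#' @param hard_gates Use hard routing (gates thresholded at the configured
#'   `gate_threshold`) instead of the soft convex blend.
#' @return List with `logits` (numeric vector), `prob`
#'   (`sigmoid(logits)`), and `bundle` (one interpretability record per
#'   volume).
#' @export
model_forward <- function(model, batch, hard_gates = FALSE) {
  if (!inherits(batch, "cvit_batch")) batch <- volume_batch(batch)
  d_expect <- model$config$input_shape
  logits <- numeric(length(batch$volumes))
  bundles <- vector("list", length(batch$volumes))
  for (i in seq_along(batch$volumes)) {
    v <- batch$volumes[[i]]
    if (!all(dim(v)[1:3] == d_expect)) {
      stop("input stage: volume ", i, " has extent ",
           paste(dim(v)[1:3], collapse = "x"), " but the model expects ",
           paste(d_expect, collapse = "x"), call. = FALSE)
    }
    f <- model.fwd_sample(model, v, hard_gates = hard_gates)
    logits[i] <- f$logit
    bundles[[i]] <- f$bundle
  }
  list(logits = logits, prob = sigmoid(logits), bundle = bundles)
}

#' Count trainable parameters analytically
#'
#' Computes the parameter count of every layer from the configuration alone
#' (closed-form arithmetic, no instantiation) and returns the per-layer table
#' plus the total. For an instantiated model the total equals the number of
#' elements actually allocated.
#'
#' @param config A [cvit_config()].
#' @return A tibble with columns `layer`, `group`, `params`, plus attribute
#'   `total`; use `sum(out$params)` or `attr(out, "total")`.
#' @export
count_params <- function(config) {
  cfg <- config
  k3 <- 27L
  cs <- cfg$stem_channels
  rows <- list()
  add <- function(layer, group, n) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(layer = layer, group = group,
                                                 params = as.numeric(n))
  }
  for (c in 1:5) {
    nm <- cvit_sequences()[c]
    add(paste0("caeff/", nm, "/conv"), "caeff", k3 * 1 * cs + cs)
    if (c == 2L) {
      r <- cs %/% cfg$se_reduction
      add(paste0("caeff/", nm, "/se"), "caeff", cs * r + r + r * cs + cs)
    } else {
      add(paste0("caeff/", nm, "/gate"), "caeff", 1 * 1 + 1)
      # depthwise on 1 channel + pointwise 1 -> cs (gcd = 1)
      add(paste0("caeff/", nm, "/dsgc"), "caeff", (k3 * 1 + 1) + (1 * cs + cs))
    }
  }
  c_prev <- 5L * cs
  for (i in seq_along(cfg$msfe_channels)) {
    c_out <- cfg$msfe_channels[i]
    g <- gcd_int(c_prev, c_out)
    add(paste0("msfe", i, "/gn"), "msfe", c_prev * c_prev + c_prev)
    add(paste0("msfe", i, "/dsgc"), "msfe",
        (k3 * c_prev + c_prev) + ((c_prev %/% g) * c_out + c_out))
    c_prev <- c_out
  }
  shp <- cvit_shapes(cfg)
  v <- shp$tokens[1] - 1L
  e <- cfg$embed_dim
  add("tokenizer", "tokenizer", c_prev * e + e + e + (v + 1L) * e)
  hidden <- as.integer(round(cfg$mlp_ratio * e))
  for (i in seq_len(cfg$depth)) {
    add(paste0("block", i, "/ln"), "encoder", 4 * e)
    add(paste0("block", i, "/attn"), "encoder", 4 * (e * e + e))
    add(paste0("block", i, "/mlp"), "encoder",
        e * hidden + hidden + hidden * e + e)
  }
  half <- max(1L, e %/% 2L)
  add("head", "head", e * e + e + 2 * e + e * half + half + half + 1)
  out <- dplyr::bind_rows(rows)
  attr(out, "total") <- sum(out$params)
  out
}

# binary cross-entropy on logits, numerically stable, with gradient
bce_with_logits <- function(logits, labels) {
  l <- logits
  loss <- mean(pmax(l, 0) - l * labels + log1p(exp(-abs(l))))
  grad <- (sigmoid(l) - labels) / length(l)
  list(loss = loss, grad = grad)
}
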