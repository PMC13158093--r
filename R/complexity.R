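#' Convolution specification
#'
#' Kernel extents, padding, stride and channel counts of one 3D convolution,
#' the symbols of the shape and FLOPs formulas.
#'
#' @param k1,k2,k3 Kernel extents (voxels) along depth, height, width.
#' @param c_in,c_out Input and output channel counts.
#' @param pad Symmetric zero padding (voxels).
#' @param stride Stride.
#' @return A `conv_spec` list.
#' @export
conv_spec <- function(k1 = 3L, k2 = k1, k3 = k1, c_in = 1L, c_out = 1L,
                      pad = 0L, stride = 1L) {
  spec <- list(k1 = as.integer(k1), k2 = as.integer(k2), k3 = as.integer(k3),
               c_in = as.integer(c_in), c_out = as.integer(c_out),
               pad = as.integer(pad), stride = as.integer(stride))
  stopifnot(spec$k1 >= 1L, spec$k2 >= 1L, spec$k3 >= 1L,
            spec$c_in >= 1L, spec$c_out >= 1L,
            spec$pad >= 0L, spec$stride >= 1L)
  structure(spec, class = "conv_spec")
}

#' Output shape of a 3D convolution
#'
#' Each spatial output extent is `floor((in + 2*P - K) / S) + 1`, the number
#' of valid sliding-window placements of the kernel on the padded input.
#'
#' @param shape Integer vector `(D_in, H_in, W_in)`.
#' @param spec A [conv_spec()].
#' @return Integer vector `(D_out, H_out, W_out)`.
#' @export
conv_output_shape <- function(shape, spec) {
  stopifnot(length(shape) == 3L)
  k <- c(spec$k1, spec$k2, spec$k3)
  out <- (as.integer(shape) + 2L * spec$pad - k) %/% spec$stride + 1L
  axes <- c("depth", "height", "width")
  bad <- which(out <= 0L)
  if (length(bad) > 0L) {
    stop("non-positive output extent on ", axes[bad[1]],
         " axis (input ", shape[bad[1]], ", kernel ", k[bad[1]],
         ", pad ", spec$pad, ", stride ", spec$stride, ")", call. = FALSE)
  }
  out
}

#' Multiply count of a standard 3D convolution
#'
#' `K1*K2*K3 * C_in * C_out * D_out*H_out*W_out`, counting multiply
#' operations only (use `mult_add = TRUE` to count multiply-adds as 2).
#'
#' @param spec A [conv_spec()].
#' @param out_shape Output spatial extents, normally from
#'   [conv_output_shape()].
#' @param mult_add Count each multiply-accumulate as 2 operations.
#' @return Exact whole number (double; exact up to 2^53).
#' @export
flops_standard <- function(spec, out_shape, mult_add = FALSE) {
  v <- prod(as.numeric(out_shape))
  n <- as.numeric(spec$k1) * spec$k2 * spec$k3 * spec$c_in * spec$c_out * v
  if (mult_add) n <- 2 * n
  n
}

#' Multiply count of a depthwise separable group convolution
#'
#' Depthwise term `K1*K2*K3 * C_in * V` plus grouped-pointwise term
#' `V * C_out * C_in / gcd(C_in, C_out)`, with `V` the output voxel count.
#'
#' @inheritParams flops_standard
#' @return Exact whole number.
#' @export
flops_dsgc <- function(spec, out_shape, mult_add = FALSE) {
  v <- prod(as.numeric(out_shape))
  g <- gcd_int(spec$c_in, spec$c_out)
  n <- as.numeric(spec$k1) * spec$k2 * spec$k3 * spec$c_in * v +
    v * spec$c_out * (spec$c_in / g)
  if (mult_add) n <- 2 * n
  n
}

#' FLOPs reduction ratio of the separable grouped convolution
#'
#' Closed form `1/C_out + 1/(gcd(C_in, C_out) * K1*K2*K3)`, i.e. the ratio of
#' the separable to the standard multiply count. Below 1 whenever
#' `C_out >= 2` and the kernel is non-trivial; for `C_out = 1` the ratio is
#' `1 + 1/K^3` (no saving) and a warning is raised.
#'
#' @param spec A [conv_spec()].
#' @return Ratio as a double.
#' @export
reduction_ratio <- function(spec) {
  g <- gcd_int(spec$c_in, spec$c_out)
  k3 <- as.numeric(spec$k1) * spec$k2 * spec$k3
  r <- 1 / spec$c_out + 1 / (g * k3)
  if (r >= 1) {
    warning("separable grouped convolution saves nothing for this spec ",
            "(ratio ", format(r), ")", call. = FALSE)
  }
  r
}

attn_flops <- function(n_tokens, embed_dim, num_heads, mult_add = FALSE) {
  n <- as.numeric(n_tokens); e <- as.numeric(embed_dim)
  # QKV projections + two attention matmuls + output projection
  f <- 3 * n * e * e + 2 * n * n * e + n * e * e
  if (mult_add) 2 * f else f
}

mlp_flops <- function(n_tokens, embed_dim, hidden, mult_add = FALSE) {
  f <- as.numeric(n_tokens) * embed_dim * hidden * 2
  if (mult_add) 2 * f else f
}

#' Per-layer complexity report of a model configuration
#'
#' Walks the architecture and reports, per layer, the analytic parameter
#' count and multiply count: convolution layers via the standard/separable
#' formulas, attention and feed-forward layers via matrix-multiply counting
#' (QKV projections, two attention products, output projection, two MLP
#' products; biases, softmax and normalization are not counted).
#'
#' @param config A [cvit_config()].
#' @param mult_add Count multiply-adds as 2 operations.
#' @return A `cvit_complexity` tibble with columns `layer`, `group`,
#'   `params`, `flops`, and for routed convolution stages `flops_standard`,
#'   `flops_dsgc` and `reduction`; attributes `total_params`, `total_flops`.
#' @export
model_complexity_report <- function(config, mult_add = FALSE) {
  cfg <- config
  pt <- count_params(cfg)
  shapes <- cvit_shapes(cfg)
  cs <- cfg$stem_channels
  rows <- list()
  add <- function(layer, group, flops, fstd = NA_real_, fdsgc = NA_real_) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      layer = layer, group = group, flops = flops,
      flops_standard = fstd, flops_dsgc = fdsgc,
      reduction = ifelse(is.na(fstd), NA_real_, fdsgc / fstd))
  }
  out1 <- shapes$caeff[1:3]
  for (c in 1:5) {
    nm <- cvit_sequences()[c]
    sp <- conv_spec(3L, c_in = 1L, c_out = cs, pad = 1L,
                    stride = cfg$caeff_stride)
    fstd <- flops_standard(sp, out1, mult_add)
    if (c == 2L) {
      add(paste0("caeff/", nm), "caeff", fstd)
    } else {
      fdsgc <- flops_dsgc(sp, out1, mult_add)
      # soft routing evaluates both paths
      add(paste0("caeff/", nm), "caeff", fstd + fdsgc, fstd, fdsgc)
    }
  }
  c_prev <- 5L * cs
  d <- out1
  for (i in seq_along(cfg$msfe_channels)) {
    c_out <- cfg$msfe_channels[i]
    sp <- conv_spec(3L, c_in = c_prev, c_out = c_out, pad = 1L,
                    stride = cfg$msfe_stride)
    d <- conv_output_shape(d, sp)
    fstd <- flops_standard(sp, d, mult_add)
    fdsgc <- flops_dsgc(sp, d, mult_add)
    add(paste0("msfe", i), "msfe", fdsgc, fstd, fdsgc)
    c_prev <- c_out
  }
  n_tok <- shapes$tokens[1]
  e <- cfg$embed_dim
  v <- n_tok - 1L
  f_tok <- as.numeric(v) * c_prev * e
  if (mult_add) f_tok <- 2 * f_tok
  add("tokenizer", "tokenizer", f_tok)
  hidden <- as.integer(round(cfg$mlp_ratio * e))
  for (i in seq_len(cfg$depth)) {
    add(paste0("block", i, "/attn"), "encoder",
        attn_flops(n_tok, e, cfg$num_heads, mult_add))
    add(paste0("block", i, "/mlp"), "encoder",
        mlp_flops(n_tok, e, hidden, mult_add))
  }
  half <- max(1L, e %/% 2L)
  f_head <- e * e + e * half + half
  if (mult_add) f_head <- 2 * f_head
  add("head", "head", as.numeric(f_head))
  out <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(out, merge_block_params(pt), by = "layer")
  out <- dplyr::select(out, "layer", "group", "params", dplyr::everything())
  attr(out, "total_params") <- sum(pt$params)
  attr(out, "total_flops") <- sum(out$flops)
  class(out) <- c("cvit_complexity", class(out))
  out
}

# aggregate the fine-grained parameter table onto complexity-report layers
merge_block_params <- function(pt) {
  key <- pt$layer
  key <- sub("^caeff/([^/]+)/.*$", "caeff/\\1", key)
  key <- sub("^(msfe[0-9]+)/.*$", "\\1", key)
  key[key %in% c("tokenizer", "head")] <- key[key %in% c("tokenizer", "head")]
  is_block <- grepl("^block[0-9]+/", key)
  blk <- sub("^(block[0-9]+)/.*$", "\\1", key[is_block])
  part <- sub("^block[0-9]+/", "", key[is_block])
  # ln params belong half to attn, half to mlp sublayer rows; simpler and
  # documented: attach all block params to the attn row, mlp row gets mlp only
  key[is_block] <- paste0(blk, "/", ifelse(part == "mlp", "mlp", "attn"))
  agg <- stats::aggregate(list(params = pt$params), by = list(layer = key), sum)
  tibble::as_tibble(agg)
}
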