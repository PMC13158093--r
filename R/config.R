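#' Canonical MRI sequence order
#'
#' The five input contrasts, in the fixed channel order the network expects:
#' contrast-enhanced T1, plain T1, T2, FLAIR, and the apparent diffusion
#' coefficient map.
#'
#' @return Character vector of length 5.
#' @export
cvit_sequences <- function() {
  c("CE-T1WI", "T1WI", "T2WI", "FLAIR", "ADC")
}

#' Architectural configuration for the 3D C-Vit network
#'
#' Assembles and validates the full hyperparameter record of the hybrid
#' CNN/transformer: the channel-attention fusion stem (one convolutional path
#' per MRI sequence, squeeze-and-excitation on the T1WI path, gated routing of
#' the others between a standard convolution and a depthwise separable group
#' convolution), the multi-scale extraction stages, and the transformer
#' encoder over a CLS token.
#'
#' @param preset `"desk"` (small dimensions suitable for CPU work; embedding
#'   width 96, 2 encoder layers, 4 heads) or `"paper"` (embedding width 768,
#'   8 encoder layers, 12 heads, head size 64). The published width/depth of
#'   the `"paper"` preset is retained verbatim even though it cannot be
#'   reconciled with the published 1.82 M parameter total; see the package
#'   vignette.
#' @param input_shape Integer (D, H, W) extent of the input volumes in voxels.
#' @param stem_channels Output channels of each per-sequence fusion path.
#' @param msfe_channels Integer vector, output channels of each multi-scale
#'   extraction stage (one stage per element).
#' @param embed_dim,depth,num_heads,mlp_ratio Transformer encoder dimensions.
#' @param se_reduction Bottleneck reduction of the squeeze-and-excitation
#'   block; must divide `stem_channels`.
#' @param gate_threshold Threshold used by the optional hard-routing inference
#'   mode; gates at or above it select the standard-convolution path.
#' @param dropout Dropout probability (training only; 0 disables).
#' @param caeff_stride,msfe_stride Spatial stride of the fusion stem and of
#'   each extraction stage.
#' @return A `cvit_config` list.
#' @examples
#' cfg <- cvit_config("desk")
#' cfg$embed_dim / cfg$num_heads  # attention head size
#' @export
cvit_config <- function(preset = c("desk", "paper"),
                        input_shape = c(16L, 64L, 64L),
                        stem_channels = NULL,
                        msfe_channels = NULL,
                        embed_dim = NULL,
                        depth = NULL,
                        num_heads = NULL,
                        mlp_ratio = NULL,
                        se_reduction = NULL,
                        gate_threshold = 0.5,
                        dropout = 0,
                        caeff_stride = 2L,
                        msfe_stride = 2L) {
  preset <- match.arg(preset)
  defaults <- if (preset == "desk") {
    list(stem_channels = 4L, msfe_channels = c(32L, 64L), embed_dim = 96L,
         depth = 2L, num_heads = 4L, mlp_ratio = 2, se_reduction = 2L)
  } else {
    list(stem_channels = 16L, msfe_channels = c(256L, 768L), embed_dim = 768L,
         depth = 8L, num_heads = 12L, mlp_ratio = 4, se_reduction = 16L)
  }
  pick <- function(x, d) if (is.null(x)) d else x
  cfg <- list(
    preset = preset,
    in_sequences = cvit_sequences(),
    input_shape = as.integer(input_shape),
    stem_channels = as.integer(pick(stem_channels, defaults$stem_channels)),
    msfe_channels = as.integer(pick(msfe_channels, defaults$msfe_channels)),
    embed_dim = as.integer(pick(embed_dim, defaults$embed_dim)),
    depth = as.integer(pick(depth, defaults$depth)),
    num_heads = as.integer(pick(num_heads, defaults$num_heads)),
    mlp_ratio = pick(mlp_ratio, defaults$mlp_ratio),
    se_reduction = as.integer(pick(se_reduction, defaults$se_reduction)),
    gate_threshold = gate_threshold,
    dropout = dropout,
    caeff_stride = as.integer(caeff_stride),
    msfe_stride = as.integer(msfe_stride),
    num_outputs = 1L
  )
  class(cfg) <- "cvit_config"
  validate_cvit_config(cfg)
  cfg
}

validate_cvit_config <- function(cfg) {
  stopifnot(
    length(cfg$in_sequences) == 5L,
    length(cfg$input_shape) == 3L, all(cfg$input_shape >= 1L),
    cfg$stem_channels >= 1L,
    length(cfg$msfe_channels) >= 1L, all(cfg$msfe_channels >= 1L),
    cfg$embed_dim >= 1L, cfg$depth >= 1L, cfg$num_heads >= 1L,
    cfg$mlp_ratio > 0,
    cfg$se_reduction >= 1L,
    cfg$gate_threshold >= 0, cfg$gate_threshold <= 1,
    cfg$dropout >= 0, cfg$dropout < 1,
    cfg$num_outputs == 1L
  )
  if (cfg$embed_dim %% cfg$num_heads != 0L) {
    stop("embed_dim (", cfg$embed_dim, ") must be divisible by num_heads (",
         cfg$num_heads, ")", call. = FALSE)
  }
  if (cfg$stem_channels %% cfg$se_reduction != 0L) {
    stop("stem_channels (", cfg$stem_channels,
         ") must be divisible by se_reduction (", cfg$se_reduction, ")",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cvit_config <- function(x, ...) {
  cat("<cvit_config: ", x$preset, " preset>\n", sep = "")
  cat("  input: 5 x ", paste(x$input_shape, collapse = " x "),
      " (", paste(x$in_sequences, collapse = ", "), ")\n", sep = "")
  cat("  fusion stem: ", x$stem_channels, " ch/path, stride ", x$caeff_stride,
      "; extraction stages: ", paste(x$msfe_channels, collapse = " -> "),
      " ch, stride ", x$msfe_stride, "\n", sep = "")
  cat("  encoder: width ", x$embed_dim, ", depth ", x$depth, ", ",
      x$num_heads, " heads (head size ", x$embed_dim %/% x$num_heads,
      "), mlp ratio ", x$mlp_ratio, "\n", sep = "")
  invisible(x)
}

#' Attention head size of a configuration
#'
#' @param config A [cvit_config()].
#' @return Integer head size, `embed_dim / num_heads`.
#' @export
head_dim <- function(config) {
  config$embed_dim %/% config$num_heads
}
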