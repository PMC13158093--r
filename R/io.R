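# NIfTI subject I/O and the preprocessing stand-ins. Registration and bias
# correction are upstream responsibilities: sequences arriving on different
# grids are refused, never silently registered.

#' Read one subject's five registered sequences
#'
#' Loads five NIfTI files (plus an optional mask), checks that all share one
#' grid and affine, and stacks them in canonical sequence order regardless of
#' the order the paths were supplied in.
#'
#' @param paths Named character vector or list of five file paths; names must
#'   be the sequence tags of [cvit_sequences()].
#' @param mask_path Optional path to a binary mask NIfTI.
#' @return List with `volume` (`(D, H, W, 5)` array), `mask` (or `NULL`),
#'   `spacing` (mm) and `affine`.
#' @export
read_subject <- function(paths, mask_path = NULL) {
  paths <- unlist(paths)
  if (!setequal(names(paths), cvit_sequences())) {
    stop("paths must be named with the five sequence tags: ",
         paste(cvit_sequences(), collapse = ", "), call. = FALSE)
  }
  paths <- paths[cvit_sequences()]
  imgs <- lapply(paths, RNifti::readNifti)
  ref_dim <- dim(imgs[[1]])
  ref_aff <- RNifti::xform(imgs[[1]])
  for (i in seq_along(imgs)[-1]) {
    if (!identical(dim(imgs[[i]]), ref_dim)) {
      stop("grid mismatch: '", paths[i], "' has extent ",
           paste(dim(imgs[[i]]), collapse = "x"), " but '", paths[1],
           "' has ", paste(ref_dim, collapse = "x"), call. = FALSE)
    }
    if (max(abs(RNifti::xform(imgs[[i]]) - ref_aff)) > 1e-4) {
      stop("affine mismatch: '", paths[i], "' is not aligned with '",
           paths[1], "'", call. = FALSE)
    }
  }
  vol <- array(0, dim = c(ref_dim, 5L))
  for (i in 1:5) vol[, , , i] <- as.array(imgs[[i]])
  mask <- NULL
  if (!is.null(mask_path)) {
    mimg <- RNifti::readNifti(mask_path)
    if (!identical(dim(mimg), ref_dim)) {
      stop("grid mismatch: mask '", mask_path, "' has extent ",
           paste(dim(mimg), collapse = "x"), call. = FALSE)
    }
    mask <- as.array(mimg)
  }
  list(volume = vol, mask = mask,
       spacing = RNifti::pixdim(imgs[[1]]), affine = ref_aff)
}

#' Write one subject's sequences as NIfTI files
#'
#' @param volume `(D, H, W, 5)` array in canonical order.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @param mask Optional `(D, H, W)` mask.
#' @param spacing Voxel spacing in mm.
#' @return Named vector of the written paths.
#' @export
write_subject <- function(volume, dir, prefix = "subject", mask = NULL,
                          spacing = c(1, 1, 1)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (i in 1:5) {
    tag <- gsub("-", "", cvit_sequences()[i])
    p <- file.path(dir, paste0(prefix, "_", tag, ".nii.gz"))
    img <- RNifti::asNifti(volume[, , , i])
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, p)
    paths[cvit_sequences()[i]] <- p
  }
  if (!is.null(mask)) {
    p <- file.path(dir, paste0(prefix, "_mask.nii.gz"))
    mimg <- RNifti::asNifti(mask)
    RNifti::pixdim(mimg) <- spacing
    RNifti::writeNifti(mimg, p)
    paths["mask"] <- p
  }
  paths
}

#' Resample a volume to a target voxel spacing
#'
#' Trilinear interpolation for intensity volumes, nearest neighbor for masks
#' (preserving the \{0, 1\} value set). The output grid is
#' `ceil(extent_mm / spacing)` voxels per axis and the world origin (center
#' of voxel 1) is preserved.
#'
#' @param volume 3D numeric array.
#' @param spacing Current voxel spacing in mm, length 3.
#' @param target Target voxel spacing in mm, length 3.
#' @param mode `"trilinear"` or `"nearest"`.
#' @return Resampled 3D array with attribute `spacing`.
#' @export
resample_to_spacing <- function(volume, spacing, target,
                                mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(all(spacing > 0), all(target > 0))
  d <- dim(volume)
  if (any(d == 0L)) stop("zero-extent axis in input volume", call. = FALSE)
  extent_mm <- d * spacing
  d_out <- pmax(as.integer(ceiling(extent_mm / target)), 1L)
  # voxel-center coordinates: world(i) = (i - 1) * spacing
  coords <- lapply(1:3, function(ax) {
    ((seq_len(d_out[ax]) - 1) * target[ax]) / spacing[ax] + 1
  })
  gi <- rep(coords[[1]], times = d_out[2] * d_out[3])
  gj <- rep(rep(coords[[2]], each = d_out[1]), times = d_out[3])
  gk <- rep(coords[[3]], each = d_out[1] * d_out[2])
  if (mode == "nearest") {
    ii <- pmin(pmax(round(gi), 1), d[1])
    jj <- pmin(pmax(round(gj), 1), d[2])
    kk <- pmin(pmax(round(gk), 1), d[3])
    out <- volume[cbind(ii, jj, kk)]
  } else {
    i0 <- pmin(pmax(floor(gi), 1), d[1]); i1 <- pmin(i0 + 1, d[1])
    j0 <- pmin(pmax(floor(gj), 1), d[2]); j1 <- pmin(j0 + 1, d[2])
    k0 <- pmin(pmax(floor(gk), 1), d[3]); k1 <- pmin(k0 + 1, d[3])
    fi <- pmin(pmax(gi - i0, 0), 1)
    fj <- pmin(pmax(gj - j0, 0), 1)
    fk <- pmin(pmax(gk - k0, 0), 1)
    v <- function(a, b, c) volume[cbind(a, b, c)]
    out <-
      (1 - fi) * (1 - fj) * (1 - fk) * v(i0, j0, k0) +
      fi * (1 - fj) * (1 - fk) * v(i1, j0, k0) +
      (1 - fi) * fj * (1 - fk) * v(i0, j1, k0) +
      fi * fj * (1 - fk) * v(i1, j1, k0) +
      (1 - fi) * (1 - fj) * fk * v(i0, j0, k1) +
      fi * (1 - fj) * fk * v(i1, j0, k1) +
      (1 - fi) * fj * fk * v(i0, j1, k1) +
      fi * fj * fk * v(i1, j1, k1)
  }
  out <- array(out, dim = d_out)
  attr(out, "spacing") <- target
  out
}

#' Modal-window z-score intensity normalization
#'
#' A linear intensity normalization standing in for white-matter-referenced
#' methods: the histogram mode of the volume (256 equal bins over the
#' intensity range) defines a window of width `2 * window_frac` of the range
#' around the dominant-tissue intensity; the volume is z-scored by the mean
#' and SD of the voxels inside that window. Because the window is defined
#' relative to the range, the map is exactly invariant to affine intensity
#' transforms: `normalize(a*v + b)` equals `normalize(v)` for `a > 0`.
#'
#' @param volume 3D numeric array; must not be constant.
#' @param window_frac Half-width of the modal window as a fraction of the
#'   intensity range (default 0.05).
#' @return List with `volume` (normalized) and `params`
#'   (`mu`, `sigma`, `mode`, `window`, `method = "modal_zscore"`).
#' @export
normalize_intensity <- function(volume, window_frac = 0.05) {
  rng <- range(volume)
  if (rng[1] == rng[2]) {
    stop("constant volume cannot be normalized", call. = FALSE)
  }
  breaks <- seq(rng[1], rng[2], length.out = 257L)
  counts <- graphics::hist(volume, breaks = breaks, plot = FALSE)$counts
  mode_center <- (breaks[which.max(counts)] + breaks[which.max(counts) + 1]) / 2
  half <- window_frac * (rng[2] - rng[1])
  inside <- abs(volume - mode_center) <= half
  mu <- mean(volume[inside])
  sigma <- stats::sd(volume[inside])
  if (!is.finite(sigma) || sigma == 0) {
    # degenerate window (e.g. quantized data): widen until usable
    sigma <- stats::sd(volume)
    mu <- mean(volume)
  }
  list(volume = (volume - mu) / sigma,
       params = list(mu = mu, sigma = sigma, mode = mode_center,
                     window = c(mode_center - half, mode_center + half),
                     method = "modal_zscore"))
}

#' Cosine annealing learning rate
#'
#' `lr = base_lr * (1 + cos(pi * epoch / total)) / 2`, annealing from
#' `base_lr` at epoch 0 to 0 at the final epoch.
#'
#' @param epoch Epoch index in `[0, total_epochs]`.
#' @param total_epochs Total number of epochs.
#' @param base_lr Initial learning rate.
#' @return Learning rate.
#' @export
cosine_lr <- function(epoch, total_epochs, base_lr = 1e-4) {
  stopifnot(all(epoch >= 0), all(epoch <= total_epochs))
  base_lr * (1 + cos(pi * epoch / total_epochs)) / 2
}
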