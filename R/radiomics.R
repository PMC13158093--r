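#' First-order intensity features of a masked region
#'
#' Minimal first-order feature set over the voxels inside a binary mask:
#' mean, population variance, skewness, kurtosis, energy (sum of squares),
#' histogram entropy over a fixed 32-bin histogram, 10th/90th percentiles,
#' voxel count and physical volume. For a constant region skewness and
#' kurtosis are undefined and reported as 0 with the `degenerate` flag set.
#'
#' @param volume 3D numeric array of intensities.
#' @param mask Binary 3D array, same shape as `volume`, at least one voxel.
#' @param voxel_volume Physical volume of one voxel (e.g. mm^3).
#' @param prefix Optional name prefix (sequence tag) for the feature names.
#' @return A one-row tibble of named features (plus `degenerate` flag).
#' @export
first_order_features <- function(volume, mask, voxel_volume = 1,
                                 prefix = NULL) {
  stopifnot(all(dim(volume) == dim(mask)))
  if (sum(mask) == 0) stop("empty mask: no voxels to summarize", call. = FALSE)
  x <- volume[mask == 1]
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2) # population convention
  degenerate <- v == 0
  if (degenerate) {
    skew <- 0; kurt <- 0
  } else {
    skew <- mean((x - mu)^3) / v^1.5
    kurt <- mean((x - mu)^4) / v^2
  }
  if (degenerate) {
    entropy <- 0
  } else {
    h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = 33L),
                        plot = FALSE)$counts
    p <- h[h > 0] / n
    entropy <- -sum(p * log2(p))
  }
  q <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
  out <- tibble::tibble(
    mean = mu, variance = v, skewness = skew, kurtosis = kurt,
    energy = sum(x^2), entropy = entropy,
    p10 = q[1], p90 = q[2],
    voxel_count = n, volume = n * voxel_volume,
    degenerate = degenerate
  )
  if (!is.null(prefix)) {
    names(out) <- paste0(prefix, "_firstorder_", names(out))
  }
  out
}

#' Chi-square univariate feature filter
#'
#' Dichotomizes each continuous feature at its median and tests the 2x2
#' association with the binary label by Pearson chi-square (no continuity
#' correction). Features with p below `alpha` pass. Constant features cannot
#' be split and automatically fail (p = 1) with a warning.
#'
#' @param x Data frame or matrix of features (samples x features).
#' @param labels Binary labels.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with `feature`, `p`, `pass`.
#' @export
chi2_filter <- function(x, labels, alpha = 0.05) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(labels), all(labels %in% c(0, 1)))
  p <- vapply(seq_along(x), function(j) {
    v <- x[[j]]
    med <- stats::median(v)
    hi <- v > med
    if (all(hi) || !any(hi)) {
      warning("constant (or unsplittable) feature '", names(x)[j],
              "' fails the filter", call. = FALSE)
      return(1)
    }
    tab <- table(factor(hi, levels = c(FALSE, TRUE)),
                 factor(labels, levels = c(0, 1)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }, numeric(1))
  tibble::tibble(feature = names(x), p = p, pass = p < alpha)
}

#' LASSO feature selection with cross-validation
#'
#' L1-penalized logistic regression over a log-spaced lambda path (100
#' points, four decades below the smallest all-zero lambda), with the optimal
#' lambda chosen by k-fold cross-validated binomial deviance (lambda.min
#' rule). Features are standardized internally, so selection is invariant to
#' column scaling. Nonzero coefficients at the optimum define the selected
#' set, ranked by absolute coefficient.
#'
#' @param x Data frame or matrix of features (samples x features).
#' @param labels Binary labels.
#' @param folds Number of CV folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return A `cvit_selection` list: `coefficients` tibble (feature,
#'   coefficient, selected), `lambda_opt`, `lambda_path`, `cv_deviance`,
#'   `cv_se`, `fit` (the underlying cv.glmnet object), `n_selected`.
#' @export
lasso_select <- function(x, labels, folds = 5L, seed = 1L) {
  xm <- as.matrix(x)
  stopifnot(nrow(xm) == length(labels), all(labels %in% c(0, 1)))
  if (nrow(xm) < folds) {
    stop("fewer samples (", nrow(xm), ") than folds (", folds, ")",
         call. = FALSE)
  }
  if (folds < 2L) stop("need at least 2 folds", call. = FALSE)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), nrow(xm)))
  fit <- glmnet::cv.glmnet(xm, labels, family = "binomial",
                           alpha = 1, standardize = TRUE,
                           nlambda = 100L, lambda.min.ratio = 1e-4,
                           type.measure = "deviance", foldid = foldid)
  co <- as.numeric(stats::coef(fit, s = "lambda.min"))[-1] # drop intercept
  names(co) <- colnames(xm)
  res <- list(
    coefficients = tibble::tibble(feature = colnames(xm), coefficient = co,
                                  selected = co != 0),
    lambda_opt = fit$lambda.min,
    lambda_path = fit$lambda,
    cv_deviance = fit$cvm,
    cv_se = fit$cvsd,
    nonzero_path = fit$nzero,
    n_selected = sum(co != 0),
    fit = fit
  )
  class(res) <- "cvit_selection"
  res
}

#' @export
print.cvit_selection <- function(x, ...) {
  cat("<cvit_selection: ", x$n_selected, " of ", nrow(x$coefficients),
      " features selected at lambda = ", signif(x$lambda_opt, 4), ">\n",
      sep = "")
  invisible(x)
}

#' Rank selected features by absolute coefficient
#'
#' Descending absolute LASSO coefficient with a deterministic alphabetical
#' tie-break; the sequence-of-origin tag is parsed from the feature name
#' (`<sequence>_<rest>` convention).
#'
#' @param result A [lasso_select()] result.
#' @param top_k Keep at most this many features (default all).
#' @return A tibble with `rank`, `feature`, `coefficient`, `sequence`.
#' @export
rank_features <- function(result, top_k = Inf) {
  co <- result$coefficients
  sel <- co[co$selected, , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(tibble::tibble(rank = integer(), feature = character(),
                          coefficient = numeric(), sequence = character()))
  }
  ord <- order(-abs(sel$coefficient), sel$feature)
  sel <- sel[ord, ]
  k <- min(top_k, nrow(sel))
  sel <- sel[seq_len(k), ]
  tibble::tibble(rank = seq_len(k), feature = sel$feature,
                 coefficient = sel$coefficient,
                 sequence = sub("_.*$", "", sel$feature))
}

#' @rdname lasso_select
#' @param x A `cvit_selection` object.
#' @param ... Unused.
#' @method tidy cvit_selection
#' @export
tidy.cvit_selection <- function(x, ...) {
  out <- x$coefficients
  out[order(-abs(out$coefficient), out$feature), ]
}

#' @rdname lasso_select
#' @method glance cvit_selection
#' @export
glance.cvit_selection <- function(x, ...) {
  i <- which(x$lambda_path == x$lambda_opt)[1]
  tibble::tibble(n_features = nrow(x$coefficients),
                 n_selected = x$n_selected,
                 lambda_opt = x$lambda_opt,
                 cv_deviance_min = x$cv_deviance[i])
}
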