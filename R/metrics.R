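#' Scored predictions container
#'
#' Pairs continuous scores with binary labels and records the positive and
#' negative counts and midranks used by the rank-statistic AUC.
#'
#' @param scores Numeric vector of model scores or probabilities.
#' @param labels Binary vector (1 = positive / high grade).
#' @return A `scored_predictions` tibble with columns `score`, `label`,
#'   `rank` (midrank of the score among all scores).
#' @export
scored_predictions <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  assert_finite(scores, "scores")
  out <- tibble::tibble(score = as.numeric(scores),
                        label = as.integer(labels),
                        rank = rank(scores, ties.method = "average"))
  class(out) <- c("scored_predictions", class(out))
  out
}

#' Rank-statistic AUC
#'
#' The area under the ROC curve computed from midranks:
#' `AUC = (sum of positive-sample ranks - M(M+1)/2) / (M*N)` with `M`
#' positives and `N` negatives; ties contribute half a concordant pair.
#'
#' @param pred A [scored_predictions()] object, or a numeric score vector
#'   (then `labels` must be given).
#' @param labels Binary labels when `pred` is a bare vector.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(pred, labels = NULL) {
  if (!inherits(pred, "scored_predictions")) {
    pred <- scored_predictions(pred, labels)
  }
  m <- sum(pred$label == 1L)
  n <- sum(pred$label == 0L)
  if (m < 1L || n < 1L) {
    stop("AUC undefined: need at least one positive and one negative sample",
         call. = FALSE)
  }
  (sum(pred$rank[pred$label == 1L]) - m * (m + 1) / 2) / (m * n)
}

#' Confusion counts at a score threshold
#'
#' Scores at or above the threshold are predicted positive.
#'
#' @inheritParams auc_rank
#' @param threshold Decision threshold (default 0.5, for sigmoid
#'   probabilities).
#' @return A `confusion_counts` list with `tp`, `tn`, `fp`, `fn`.
#' @export
threshold_confusion <- function(pred, labels = NULL, threshold = 0.5) {
  if (!inherits(pred, "scored_predictions")) {
    pred <- scored_predictions(pred, labels)
  }
  predicted <- as.integer(pred$score >= threshold)
  out <- list(tp = sum(predicted == 1L & pred$label == 1L),
              tn = sum(predicted == 0L & pred$label == 0L),
              fp = sum(predicted == 1L & pred$label == 0L),
              fn = sum(predicted == 0L & pred$label == 1L),
              threshold = threshold)
  class(out) <- "confusion_counts"
  out
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and F1, the harmonic mean of precision and recall. A metric
#' whose denominator is zero is reported as `NA` with a warning, never as 0.
#'
#' @param counts A `confusion_counts` object or a list/vector with elements
#'   `tp`, `tn`, `fp`, `fn`.
#' @return A one-row tibble with columns `accuracy`, `precision`, `recall`,
#'   `f1`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  acc <- safe_div(tp + tn, total, "accuracy")
  prec <- safe_div(tp, tp + fp, "precision")
  rec <- safe_div(tp, tp + fn, "recall")
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) {
    if (!is.na(prec) && !is.na(rec)) {
      warning("F1 undefined: precision + recall is zero", call. = FALSE)
    }
    NA_real_
  } else {
    2 * prec * rec / (prec + rec)
  }
  tibble::tibble(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

# fast DeLong structural components: V10 (positives), V01 (negatives)
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  all_r <- rank(c(pos, neg), ties.method = "average")
  pos_r <- rank(pos, ties.method = "average")
  neg_r <- rank(neg, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - pos_r) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - neg_r) / m
  auc <- sum(all_r[seq_len(m)]) / (m * n) - (m + 1) / (2 * n)
  list(v10 = v10, v01 = v01, auc = auc, m = m, n = n)
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two models scored on the same samples using the fast
#' DeLong covariance estimate built from midrank structural components, with
#' a two-sided normal p-value for the AUC difference.
#'
#' @param pred_a,pred_b [scored_predictions()] on identical labels (same
#'   samples, same order).
#' @return A one-row tibble with `auc_a`, `auc_b`, `delta`, `z`, `p`.
#' @export
delong_test <- function(pred_a, pred_b) {
  stopifnot(nrow(pred_a) == nrow(pred_b))
  if (!all(pred_a$label == pred_b$label)) {
    stop("the two score vectors must share the same samples and labels",
         call. = FALSE)
  }
  labels <- pred_a$label
  ca <- delong_components(pred_a$score, labels)
  cb <- delong_components(pred_b$score, labels)
  m <- ca$m; n <- ca$n
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  s <- s10 / m + s01 / n
  var_delta <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  delta <- ca$auc - cb$auc
  if (var_delta <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(auc_a = ca$auc, auc_b = cb$auc, delta = delta, z = z, p = p)
}

#' Chi-square test on a contingency table
#'
#' Pearson chi-square test of independence, `sum((O-E)^2 / E)` with
#' `df = (r-1)(c-1)`. No continuity correction by default; `yates = TRUE`
#' applies the Yates correction (2x2 tables only).
#'
#' @param tab Matrix or table of nonnegative counts.
#' @param yates Apply Yates continuity correction.
#' @return A one-row tibble with `stat`, `df`, `p`.
#' @export
chi_square_test <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has an empty row or column", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  tibble::tibble(stat = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-sided.
#'
#' @param a,b Numeric vectors, each of length at least 2.
#' @return A one-row tibble with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    return(tibble::tibble(t = 0, df = length(a) + length(b) - 2, p = 1))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}

#' Cohort summary: counts and percentages per category
#'
#' Tabulates each declared categorical covariate, overall and per group,
#' reporting `n` and the percentage (one decimal, percentage of the overall
#' total for the overall rows and of the group total for group rows).
#'
#' @param data Data frame of one row per subject.
#' @param vars Character vector of categorical column names to summarize.
#' @param group Optional grouping column name (e.g. grade).
#' @return A tibble with columns `variable`, `level`, `group` (`"overall"`
#'   included), `n`, `pct`.
#' @export
cohort_summary <- function(data, vars, group = NULL) {
  if (nrow(data) == 0L) stop("empty cohort table", call. = FALSE)
  stopifnot(all(vars %in% names(data)))
  one <- function(v, rows, label) {
    tt <- table(data[[v]][rows])
    tibble::tibble(variable = v, level = names(tt), group = label,
                   n = as.integer(tt),
                   pct = round(100 * as.integer(tt) / sum(rows), 1))
  }
  out <- list()
  all_rows <- rep(TRUE, nrow(data))
  for (v in vars) {
    out[[length(out) + 1L]] <- one(v, all_rows, "overall")
    if (!is.null(group)) {
      for (g in sort(unique(data[[group]]))) {
        out[[length(out) + 1L]] <- one(v, data[[group]] == g, as.character(g))
      }
    }
  }
  dplyr::bind_rows(out)
}
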