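#' Training configuration
#'
#' Defaults mirror the published protocol: 100 epochs, minibatches of 16,
#' base learning rate 1e-4 annealed to zero by a cosine schedule, binary
#' cross-entropy on logits. The optimizer is Adam (beta 0.9/0.999, no weight
#' decay).
#'
#' @param epochs,batch_size,base_lr,seed Training hyperparameters.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 16L, base_lr = 1e-4,
                         seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, base_lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 base_lr = base_lr, seed = as.integer(seed),
                 loss = "bce_with_logits", optimizer = "adam",
                 schedule = "cosine"),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = tree_zero_like(params), v = tree_zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_map(state$m, function(m) m / bc1)
  vhat <- tree_map(state$v, function(v) v / bc2)
  upd <- tree_map2(mhat, vhat, function(m, v) lr * m / (sqrt(v) + eps))
  list(params = tree_map2(params, upd, `-`), state = state)
}

#' Train a 3D C-Vit model
#'
#' Full-batch-shuffled minibatch training with Adam and the cosine learning
#' rate schedule; the binary cross-entropy loss is computed on logits. When a
#' validation batch is supplied, the parameters with the best validation AUC
#' are retained as the returned checkpoint; otherwise the final parameters
#' are returned. All randomness (shuffling) derives from the training seed.
#'
#' @param model A [cvit_model()].
#' @param data Training [volume_batch()] with labels.
#' @param config A [train_config()].
#' @param val_data Optional validation [volume_batch()] with labels, disjoint
#'   from `data`.
#' @param verbose Print a line per epoch.
#' @return A `cvit_fit` list: `model` (with trained parameters), `log`
#'   (per-epoch tibble: `epoch`, `lr`, `loss`, `train_accuracy`, `val_auc`,
#'   `val_accuracy`), `config`, and `best_epoch`.
#' @export
train <- function(model, data, config = train_config(), val_data = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(model, "cvit_model"), inherits(config, "train_config"))
  if (!inherits(data, "cvit_batch")) data <- volume_batch(data)
  if (is.null(data$labels)) stop("training data must carry labels", call. = FALSE)
  if (!is.null(val_data) && is.null(val_data$labels)) {
    stop("validation data must carry labels", call. = FALSE)
  }
  n <- length(data$volumes)
  y <- data$labels
  set.seed(config$seed)
  state <- adam_init(model$params)
  log_rows <- vector("list", config$epochs)
  best <- list(auc = -Inf, params = model$params, epoch = NA_integer_)
  for (epoch in seq_len(config$epochs)) {
    lr <- cosine_lr(epoch - 1L, config$epochs, config$base_lr)
    order_idx <- sample.int(n)
    losses <- c()
    logits_epoch <- numeric(n)
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- order_idx[start:min(start + config$batch_size - 1L, n)]
      gacc <- NULL
      logits <- numeric(length(idx))
      caches <- vector("list", length(idx))
      for (j in seq_along(idx)) {
        f <- model.fwd_sample(model, data$volumes[[idx[j]]], keep_cache = TRUE)
        logits[j] <- f$logit
        caches[[j]] <- f$cache
      }
      lb <- bce_with_logits(logits, y[idx])
      if (!is.finite(lb$loss)) {
        stop("training aborted: non-finite loss at epoch ", epoch,
             " (logit range ", paste(signif(range(logits), 3), collapse = " .. "),
             ")", call. = FALSE)
      }
      for (j in seq_along(idx)) {
        b <- model.bwd_sample(model, lb$grad[j], caches[[j]])
        gacc <- if (is.null(gacc)) b$grads else tree_map2(gacc, b$grads, `+`)
        caches[j] <- list(NULL)
      }
      st <- adam_step(model$params, gacc, state, lr)
      model$params <- st$params
      state <- st$state
      losses <- c(losses, lb$loss)
      logits_epoch[idx] <- logits
    }
    train_acc <- mean((logits_epoch >= 0) == (y == 1L))
    val_auc <- NA_real_; val_acc <- NA_real_
    if (!is.null(val_data)) {
      ev <- model_forward(model, val_data)
      pv <- scored_predictions(ev$prob, val_data$labels)
      val_auc <- auc_rank(pv)
      val_acc <- mean((ev$prob >= 0.5) == (val_data$labels == 1L))
      if (val_auc > best$auc) {
        best <- list(auc = val_auc, params = model$params, epoch = epoch)
      }
    }
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, loss = mean(losses),
      train_accuracy = train_acc, val_auc = val_auc, val_accuracy = val_acc)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  acc %.3f%s",
                      epoch, lr, mean(losses), train_acc,
                      if (is.na(val_auc)) "" else sprintf("  val AUC %.3f", val_auc)))
    }
  }
  if (!is.null(val_data) && is.finite(best$auc)) {
    model$params <- best$params
  }
  structure(list(model = model, log = dplyr::bind_rows(log_rows),
                 config = config, best_epoch = best$epoch),
            class = "cvit_fit")
}

#' @export
print.cvit_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat("<cvit_fit: ", nrow(x$log), " epochs, final loss ",
      signif(last$loss, 4), ", final train accuracy ",
      signif(last$train_accuracy, 4), ">\n", sep = "")
  invisible(x)
}

#' @rdname train
#' @param x A `cvit_fit` object.
#' @param ... Unused.
#' @method tidy cvit_fit
#' @export
tidy.cvit_fit <- function(x, ...) x$log

#' @rdname train
#' @method glance cvit_fit
#' @export
glance.cvit_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(epochs = nrow(x$log), final_loss = last$loss,
                 final_train_accuracy = last$train_accuracy,
                 best_val_auc = if (all(is.na(x$log$val_auc))) NA_real_
                                else max(x$log$val_auc, na.rm = TRUE),
                 best_epoch = x$best_epoch)
}

#' Evaluate a model on a labelled batch
#'
#' Runs the forward pass and computes the evaluation suite: rank-statistic
#' AUC, confusion counts at the threshold, accuracy/precision/recall/F1, and
#' ROC points. Label-free data yields a scores-only report.
#'
#' @param model A trained [cvit_model()] (or a `cvit_fit`).
#' @param data A [volume_batch()].
#' @param threshold Decision threshold on the sigmoid probability.
#' @return A `cvit_eval` list: `scores`, and with labels also `auc`,
#'   `confusion`, `metrics` (tibble), `roc` (tibble of FPR/TPR points).
#' @export
evaluate <- function(model, data, threshold = 0.5) {
  if (inherits(model, "cvit_fit")) model <- model$model
  if (!inherits(data, "cvit_batch")) data <- volume_batch(data)
  if (length(data$volumes) == 0L) stop("empty evaluation set", call. = FALSE)
  fw <- model_forward(model, data)
  out <- list(scores = fw$prob, threshold = threshold)
  if (!is.null(data$labels)) {
    pred <- scored_predictions(fw$prob, data$labels)
    cm <- threshold_confusion(pred, threshold = threshold)
    out$auc <- auc_rank(pred)
    out$confusion <- cm
    out$metrics <- classification_metrics(cm)
    out$roc <- roc_points(pred)
    out$predictions <- pred
  }
  class(out) <- "cvit_eval"
  out
}

#' ROC curve points
#'
#' @param pred A [scored_predictions()] object.
#' @return Tibble with `threshold`, `fpr`, `tpr`, one row per distinct score
#'   plus the two endpoints.
#' @export
roc_points <- function(pred) {
  th <- c(Inf, sort(unique(pred$score), decreasing = TRUE), -Inf)
  m <- sum(pred$label == 1L); n <- sum(pred$label == 0L)
  rows <- lapply(th, function(t) {
    pp <- pred$score >= t
    tibble::tibble(threshold = t,
                   fpr = sum(pp & pred$label == 0L) / n,
                   tpr = sum(pp & pred$label == 1L) / m)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.cvit_eval <- function(x, ...) {
  if (is.null(x$auc)) {
    cat("<cvit_eval: scores only, n = ", length(x$scores), ">\n", sep = "")
  } else {
    cat("<cvit_eval: AUC ", signif(x$auc, 4), ", accuracy ",
        signif(x$metrics$accuracy, 4), " at threshold ", x$threshold, ">\n",
        sep = "")
  }
  invisible(x)
}

#' @rdname evaluate
#' @param x A `cvit_eval` object.
#' @param ... Unused.
#' @method glance cvit_eval
#' @export
glance.cvit_eval <- function(x, ...) {
  if (is.null(x$auc)) return(tibble::tibble(n = length(x$scores)))
  dplyr::bind_cols(tibble::tibble(auc = x$auc), x$metrics)
}

#' Export the interpretability bundle for one subject
#'
#' Runs the forward pass on one volume and extracts: the squeeze-and-
#' excitation channel weights of the T1WI path, the routing gates of the
#' fusion stem, the modulation gates of each extraction stage, and the final
#' layer's CLS-token attention averaged over heads — reshaped to the token
#' grid (renormalized to sum to 1 after dropping the CLS self-entry) and
#' trilinearly resampled to the input grid. With `path_prefix` the map is
#' written as NIfTI next to a JSON sidecar of all scalar weights.
#'
#' @param model A trained [cvit_model()] (or `cvit_fit`).
#' @param volume A `(D, H, W, 5)` array.
#' @param path_prefix Optional output path prefix (writes
#'   `<prefix>_attention.nii.gz` and `<prefix>_weights.json`).
#' @param spacing Voxel spacing recorded in the NIfTI header.
#' @return List with `se_weights`, `gates`, `msfe_gates`, `attention_grid`
#'   (token-grid array), `attention_map` (input-grid array), `cls`; paths
#'   when written.
#' @export
export_interpretability <- function(model, volume, path_prefix = NULL,
                                    spacing = c(1, 1, 1)) {
  if (inherits(model, "cvit_fit")) model <- model$model
  fw <- model_forward(model, list(volume))
  b <- fw$bundle[[1]]
  attn_last <- b$attention[[length(b$attention)]]
  cls_row <- rowMeans(matrix(attn_last[1L, -1L, ], ncol = dim(attn_last)[3]))
  cls_row <- cls_row / sum(cls_row)
  shapes <- cvit_shapes(model$config)
  grid_tok <- shapes[[length(shapes) - 1L]][1:3]
  attn_grid <- array(cls_row, dim = grid_tok)
  ratio <- model$config$input_shape / grid_tok
  attn_map <- resample_to_spacing(attn_grid, spacing = ratio,
                                  target = c(1, 1, 1))
  attr(attn_map, "spacing") <- NULL
  out <- list(se_weights = b$se_weights, gates = b$gates,
              msfe_gates = b$msfe_gates, attention_grid = attn_grid,
              attention_map = attn_map, cls = b$cls,
              logit = fw$logits[1], prob = fw$prob[1])
  if (!is.null(path_prefix)) {
    nii_path <- paste0(path_prefix, "_attention.nii.gz")
    aimg <- RNifti::asNifti(attn_map)
    RNifti::pixdim(aimg) <- spacing
    RNifti::writeNifti(aimg, nii_path)
    json_path <- paste0(path_prefix, "_weights.json")
    jsonlite::write_json(
      list(se_weights = b$se_weights, gates = as.list(b$gates),
           msfe_gates = b$msfe_gates, logit = fw$logits[1],
           prob = fw$prob[1]),
      json_path, auto_unbox = TRUE, digits = NA)
    out$paths <- c(attention = nii_path, weights = json_path)
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS container of the parameters plus a JSON sidecar
#' of the configuration.
#'
#' @param model A [cvit_model()] or `cvit_fit`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_cvit` returns the path invisibly; `load_cvit` the model.
#' @export
save_cvit <- function(model, path) {
  if (inherits(model, "cvit_fit")) model <- model$model
  saveRDS(model, path)
  cfg <- model$config
  jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_cvit
#' @export
load_cvit <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cvit_model"))
  model
}
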