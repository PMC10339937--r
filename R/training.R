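#' Training configuration
#'
#' Mini-batch SGD with momentum. Defaults are the full-scale recipe:
#' initial learning rate 0.00125, momentum 0.9, weight decay 1e-4, batch
#' size 8 clips, 60 epochs, and per-step L2 gradient-norm clipping at 40.
#' The learning-rate schedule is constant (configurable via `lr`); the
#' loss is two-class cross-entropy on the frame-mean consensus logits.
#' The momentum formulation is the conventional coupled one:
#' `v <- momentum * v + (g + weight_decay * theta)`,
#' `theta <- theta - lr * v`, with `g` the (already clipped) loss
#' gradient.
#'
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param weight_decay L2 coefficient, applied to every trainable tensor.
#' @param batch_size clips per step.
#' @param epochs training epochs.
#' @param grad_clip_max_norm global L2 clipping threshold.
#' @param seed RNG seed for shuffling.
#' @param device compute target (only `"cpu"` is available).
#' @return an object of class `"train_config"`.
#' @export
train_config <- function(lr = 0.00125, momentum = 0.9, weight_decay = 1e-4,
                         batch_size = 8L, epochs = 60L,
                         grad_clip_max_norm = 40, seed = 1L,
                         device = "cpu") {
  stopifnot(lr >= 0, momentum >= 0, weight_decay >= 0, batch_size >= 1,
            epochs >= 1, grad_clip_max_norm > 0)
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 grad_clip_max_norm = grad_clip_max_norm,
                 seed = as.integer(seed), device = device),
            class = "train_config")
}

# prep: optional environment caching clips already converted to the
# engine (H, W, C, T) layout, so conversion happens once per clip per run
batch_of <- function(m, idx, plan, prep = NULL, pre = identity) {
  get_one <- function(i) {
    key <- m$path[i]
    if (!is.null(prep) && !is.null(prep[[key]])) return(prep[[key]])
    arr <- pre(aperm(as_array(fetch_clip(m, i, plan)), c(3L, 4L, 2L, 1L)))
    if (!is.null(prep)) prep[[key]] <- arr
    arr
  }
  arrs <- lapply(idx, get_one)
  d <- dim(arrs[[1L]])
  x <- array(0, dim = c(d[1L], d[2L], d[3L], d[4L] * length(arrs)))
  for (i in seq_along(arrs))
    x[, , , (i - 1L) * d[4L] + seq_len(d[4L])] <- arrs[[i]]
  list(x = x, labels = m$label[idx], t_frames = plan$n_frames)
}

#' Train a model
#'
#' Runs `cfg$epochs` epochs of mini-batch SGD with momentum, weight
#' decay and per-step global L2 gradient clipping over the training
#' split, logging loss and accuracy per epoch. When a validation
#' manifest is supplied, validation accuracy is tracked and the weights
#' of the best validation epoch are retained in the returned model.
#' Deterministic for a fixed `cfg$seed` (data order, and initialization
#' if the caller seeded it) up to floating-point reduction order.
#'
#' @param model a `"tsm_model"` with materialized weights (TSM optional).
#' @param train_manifest,val_manifest [clip_manifest]s; `val_manifest`
#'   may be `NULL`.
#' @param cfg a [train_config].
#' @param plan a [sampling_plan]; its `n_frames` is the frame count `T`
#'   threaded to the shift layers.
#' @param verbose print per-epoch lines.
#' @return list with elements `model` (trained) and `history` (data
#'   frame: epoch, train_loss, train_acc, val_acc).
#' @export
train <- function(model, train_manifest, val_manifest = NULL,
                  cfg = train_config(),
                  plan = sampling_plan(target_size = NULL),
                  verbose = FALSE) {
  engine_ready(model)
  if (nrow(train_manifest) == 0L) stop("empty training split")
  n <- nrow(train_manifest)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_acc = numeric(0))
  best_acc <- -Inf
  best <- NULL
  prep <- new.env(parent = emptyenv())
  sp <- split_free_prefix(model)
  restore <- local_rng(cfg$seed)
  on.exit(restore(), add = TRUE)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(n)
    losses <- c(); correct <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      b <- batch_of(train_manifest, idx, plan, prep, sp$pre)
      zero_grads(model)
      fw <- forward_model(sp$model, b$x, b$t_frames, train = TRUE)
      clip_logits <- consensus_batch(fw$out, b$t_frames)
      ls <- softmax_xent(clip_logits, b$labels)
      if (!is.finite(ls$loss))
        stop(sprintf("non-finite loss at epoch %d (lr=%g): diverged",
                     ep, cfg$lr))
      losses <- c(losses, ls$loss)
      pred <- apply(clip_logits, 2, function(z) if (z[2] > z[1]) 1L else 0L)
      correct <- correct + sum(pred == b$labels)
      dframe <- ls$grad[, rep(seq_along(idx), each = b$t_frames)] / b$t_frames
      backward_model(sp$model, fw, dframe)
      clip_gradients(model, cfg$grad_clip_max_norm)
      sgd_step(model, cfg)
    }
    val_acc <- NA_real_
    if (!is.null(val_manifest)) {
      ev <- evaluate(model, val_manifest, plan, cfg$batch_size)
      val_acc <- ev$metrics$accuracy
      if (val_acc > best_acc) {
        best_acc <- val_acc
        best <- snapshot_params(model)
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   train_acc = 100 * correct / n,
                                   val_acc = val_acc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  train %.2f%%  val %s", ep,
                      mean(losses), 100 * correct / n,
                      if (is.na(val_acc)) "-" else sprintf("%.2f%%", val_acc)))
  }
  if (!is.null(best)) model <- restore_params(model, best)
  list(model = model, history = hist)
}

#' Confusion counts and derived metrics
#'
#' `confusion_counts()` tallies TP/FP/TN/FN with label 1 (aggressive) as
#' the positive class. `metrics_report()` derives accuracy
#' `(TP+TN)/(TP+FP+TN+FN)`, recall `TP/(TP+FN)`, precision `TP/(TP+FP)`
#' and `F1 = 2*Recall*Precision/(Recall+Precision)`, reported as
#' percentages; any metric whose denominator is 0 is defined as 0.
#'
#' @param predicted,actual integer 0/1 vectors.
#' @return `confusion_counts()`: list of class `"confusion_counts"` with
#'   TP, FP, TN, FN.
#' @export
confusion_counts <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual),
            all(predicted %in% 0:1), all(actual %in% 0:1))
  structure(list(TP = sum(predicted == 1L & actual == 1L),
                 FP = sum(predicted == 1L & actual == 0L),
                 TN = sum(predicted == 0L & actual == 0L),
                 FN = sum(predicted == 0L & actual == 1L)),
            class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param counts a `"confusion_counts"`.
#' @param per_clip_latency optional informational seconds-per-clip.
#' @return `metrics_report()`: list of class `"metrics_report"` with
#'   `accuracy`, `recall`, `precision`, `f1` (percent).
#' @export
metrics_report <- function(counts, per_clip_latency = NA_real_) {
  frac <- function(num, den) if (den == 0) 0 else num / den
  total <- counts$TP + counts$FP + counts$TN + counts$FN
  acc <- frac(counts$TP + counts$TN, total)
  rec <- frac(counts$TP, counts$TP + counts$FN)
  prec <- frac(counts$TP, counts$TP + counts$FP)
  f1 <- frac(2 * rec * prec, rec + prec)
  structure(list(accuracy = 100 * acc, recall = 100 * rec,
                 precision = 100 * prec, f1 = 100 * f1,
                 per_clip_latency = per_clip_latency),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  recall %.2f%%  precision %.2f%%  F1 %.2f%%\n",
              x$accuracy, x$recall, x$precision, x$f1))
  invisible(x)
}

predict_clips <- function(model, m, plan, batch_size = 8L) {
  n <- nrow(m)
  preds <- integer(n)
  prep <- new.env(parent = emptyenv())
  sp <- split_free_prefix(model)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    b <- batch_of(m, idx, plan, prep, sp$pre)
    fw <- forward_model(sp$model, b$x, b$t_frames, train = FALSE)
    clip_logits <- consensus_batch(fw$out, b$t_frames)
    # ties break toward the negative (non-aggressive) class
    preds[idx] <- apply(clip_logits, 2,
                        function(z) if (z[2] > z[1]) 1L else 0L)
  }
  preds
}

#' Evaluate a model on a manifest
#'
#' One prediction per clip: frame logits, frame-mean consensus, argmax
#' (ties toward the negative class), then confusion counts and the
#' derived metrics. Re-running on a fixed model and manifest yields
#' identical counts.
#'
#' @param model trained `"tsm_model"`.
#' @param manifest a non-empty [clip_manifest].
#' @param plan a [sampling_plan].
#' @param batch_size clips per forward pass.
#' @return list with `counts` ([confusion_counts]) and `metrics`
#'   ([metrics_report]).
#' @export
evaluate <- function(model, manifest, plan = sampling_plan(target_size = NULL),
                     batch_size = 8L) {
  if (nrow(manifest) == 0L) stop("empty evaluation split")
  t0 <- Sys.time()
  preds <- predict_clips(model, manifest, plan, batch_size)
  lat <- as.numeric(difftime(Sys.time(), t0, units = "secs")) / nrow(manifest)
  counts <- confusion_counts(preds, manifest$label)
  list(counts = counts, metrics = metrics_report(counts, lat))
}

#' Checkpoint save/load
#'
#' Serializes the architecture spec, shift configuration and trainable
#' state to an RDS file; `load_checkpoint()` rebuilds the model handle.
#' Only engine-trainable (toy) models carry weights.
#'
#' @param model a `"tsm_model"` with materialized weights.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  engine_ready(model)
  saveRDS(list(spec = model$spec, shift = model$shift, graph = model$graph,
               params = snapshot_params(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- structure(list(spec = ck$spec, graph = ck$graph, shift = ck$shift,
                          params = NULL), class = "tsm_model")
  restore_params(model, ck$params)
}
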