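# Minimal CNN engine backing the small trainable nets. Activations use a
# dense (H, W, C, N) layout where the N axis holds the frames of a
# mini-batch clip-major (frames 1..T of clip 1, then clip 2, ...), so 2D
# layers treat frames like batch images and the shift layer regroups them
# with the explicitly threaded frame count T.

#' Build a small trainable residual network
#'
#' A compact residual CNN sharing the block structure and TSM-insertion
#' machinery of the large backbones, small enough to train on a CPU in
#' minutes: an average-pooling + strided-convolution entry that
#' downsamples aggressively, `n_blocks` identity-shortcut residual blocks
#' (3x3 conv, batch norm, ReLU, 3x3 conv, batch norm; post-addition
#' ReLU), global average pooling and a linear head. Per-frame logits are
#' aggregated by [temporal_consensus_head()].
#'
#' @param in_channels input channels (1 for grayscale clips).
#' @param channels feature channels in the trunk.
#' @param num_classes output classes.
#' @param n_blocks residual blocks.
#' @param entry_pool average-pooling factor applied to the input.
#' @param entry_stride stride of the entry convolution.
#' @return a `"tsm_model"` (weights not yet materialized; see
#'   [init_model_params()]).
#' @export
build_toy_net <- function(in_channels = 1L, channels = 10L,
                          num_classes = 2L, n_blocks = 2L,
                          entry_pool = 8L, entry_stride = 2L) {
  ch <- as.integer(channels)
  blocks <- list()
  for (b in seq_len(n_blocks)) {
    branch <- nd_seq(list(
      conv1 = nd_conv(3, ch, ch, pad = 1),
      bn1 = nd_norm("bn", ch), relu1 = nd_act("relu"),
      conv2 = nd_conv(3, ch, ch, pad = 1),
      bn2 = nd_norm("bn", ch)))
    blocks[[paste0("block", b)]] <-
      nd_block(branch, post = nd_act("relu"), insert_at = 1L)
  }
  graph <- nd_seq(list(
    stage1 = nd_seq(list(
      pool = nd_pool("avg", entry_pool),
      conv1 = nd_conv(3, in_channels, ch, stride = entry_stride, pad = 1),
      bn1 = nd_norm("bn", ch), relu1 = nd_act("relu"))),
    stage2 = nd_seq(blocks),
    head = nd_seq(list(gap = nd_gap(),
                       fc = nd_linear(ch, as.integer(num_classes))))))
  spec <- structure(list(family = "toy_residual",
                         stage_blocks = c(1L, as.integer(n_blocks)),
                         num_classes = as.integer(num_classes)),
                    class = "backbone_spec")
  structure(list(spec = spec, graph = graph, shift = NULL, params = NULL),
            class = "tsm_model")
}

param_leaf_paths <- function(model) {
  out <- list()
  walk_leaves(model$graph, function(leaf, path) {
    if (leaf$kind %in% c("conv", "norm", "linear", "layer_scale"))
      out[[paste(path, collapse = ".")]] <<- leaf
  })
  out
}

#' Materialize model weights
#'
#' Allocates and initializes the trainable tensors of a model built
#' through the graph machinery (He initialization for convolutions,
#' unit-scale/zero-offset batch norm, scaled-Gaussian linear layers).
#' Uses the current RNG state; call `set.seed()` first for reproducible
#' initialization.
#'
#' @param model a `"tsm_model"` whose layers are all engine-supported.
#' @return the model with a `params` environment attached.
#' @export
init_model_params <- function(model) {
  leaves <- param_leaf_paths(model)
  params <- new.env(parent = emptyenv())
  for (nm in names(leaves)) {
    leaf <- leaves[[nm]]
    pe <- new.env(parent = emptyenv())
    if (leaf$kind == "conv") {
      fan_in <- leaf$k * leaf$k * leaf$in_ch %/% leaf$groups
      pe$W <- matrix(rnorm(leaf$out_ch * fan_in, 0, sqrt(2 / fan_in)),
                     leaf$out_ch, fan_in)
      if (leaf$bias) pe$b <- numeric(leaf$out_ch)
    } else if (leaf$kind == "norm") {
      pe$gamma <- rep(1, leaf$c); pe$beta <- numeric(leaf$c)
      pe$running_mean <- numeric(leaf$c); pe$running_var <- rep(1, leaf$c)
    } else if (leaf$kind == "linear") {
      pe$W <- matrix(rnorm(leaf$in_f * leaf$out_f, 0, sqrt(1 / leaf$in_f)),
                     leaf$out_f, leaf$in_f)
      if (leaf$bias) pe$b <- numeric(leaf$out_f)
    } else if (leaf$kind == "layer_scale") {
      pe$gamma <- rep(1e-6, leaf$c)
    }
    assign(nm, pe, envir = params)
  }
  model$params <- params
  model
}

engine_ready <- function(model) {
  if (is.null(model$params))
    stop("model weights not materialized; call init_model_params() first")
}

bn_eps <- 1e-5
bn_momentum <- 0.1

## forward ----------------------------------------------------------------

# ctx: environment carrying caches (for backward), train flag, frame
# count, optional capture path (Grad-CAM).
forward_node <- function(node, path, x, model, ctx) {
  key <- paste(path, collapse = ".")
  out <- switch(node$kind,
    seq = {
      for (nm in names(node$children))
        x <- forward_node(node$children[[nm]], c(path, nm), x, model, ctx)
      x
    },
    pool = {
      d <- dim(x)
      ctx$caches[[key]] <- d
      avgpool_fwd(x, d[1], d[2], d[3], d[4], node$k, node$stride)
    },
    conv = {
      pe <- get(key, envir = model$params)
      d <- dim(x)
      cols <- im2col_hwcn(x, d[1], d[2], d[3], d[4], node$k, node$k,
                          node$stride, node$pad)
      ymat <- pe$W %*% cols
      if (node$bias) ymat <- ymat + pe$b
      ho <- (d[1] + 2 * node$pad - node$k) %/% node$stride + 1L
      wo <- (d[2] + 2 * node$pad - node$k) %/% node$stride + 1L
      if (ctx$need_grad) ctx$caches[[key]] <- list(cols = cols, dims = d)
      dim(ymat) <- c(node$out_ch, ho, wo, d[4])
      aperm(ymat, c(2, 3, 1, 4))
    },
    norm = {
      pe <- get(key, envir = model$params)
      d <- dim(x)
      m <- prod(d[c(1, 2, 4)])
      xm <- matrix(aperm(x, c(1, 2, 4, 3)), m, d[3])
      if (ctx$train) {
        mu <- colMeans(xm)
        xc <- xm - rep(mu, each = m)
        v <- colSums(xc * xc) / m
        pe$running_mean <- (1 - bn_momentum) * pe$running_mean + bn_momentum * mu
        pe$running_var <- (1 - bn_momentum) * pe$running_var +
          bn_momentum * v * m / max(m - 1, 1)
      } else {
        mu <- pe$running_mean; v <- pe$running_var
        xc <- xm - rep(mu, each = m)
      }
      invstd <- 1 / sqrt(v + bn_eps)
      xhat <- xc * rep(invstd, each = m)
      ym <- xhat * rep(pe$gamma, each = m) + rep(pe$beta, each = m)
      if (ctx$need_grad)
        ctx$caches[[key]] <- list(xhat = xhat, invstd = invstd, d = d,
                                  batch = ctx$train)
      dim(ym) <- d[c(1, 2, 4, 3)]
      aperm(ym, c(1, 2, 4, 3))
    },
    act = {
      y <- x * (x > 0)
      if (ctx$need_grad) ctx$caches[[key]] <- (x > 0)
      y
    },
    gap = {
      d <- dim(x)
      ctx$caches[[key]] <- d
      y <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
      matrix(y, d[3], d[4])
    },
    linear = {
      pe <- get(key, envir = model$params)
      if (ctx$need_grad) ctx$caches[[key]] <- x
      y <- pe$W %*% x
      if (node$bias) y <- y + pe$b
      y
    },
    tsm = {
      tsm_shift_hwcn(x, ctx$t_frames, model$shift, 1L)
    },
    block = {
      xin <- x
      b <- forward_node(node$branch, path, x, model, ctx)
      y <- b + xin
      if (!is.null(node$post)) {
        pkey <- paste(c(path, "relu3"), collapse = ".")
        ctx$caches[[pkey]] <- (y > 0)
        y <- y * (y > 0)
        if (identical(ctx$capture, pkey)) ctx$capture_act <- y
      }
      y
    },
    stop("engine cannot run layer kind '", node$kind, "'"))
  if (node$kind != "block" && identical(ctx$capture, key)) ctx$capture_act <- out
  out
}

forward_model <- function(model, x, t_frames, train = TRUE, capture = NULL) {
  engine_ready(model)
  ctx <- new.env(parent = emptyenv())
  ctx$caches <- list()
  ctx$train <- train
  ctx$need_grad <- train || !is.null(capture)
  ctx$t_frames <- as.integer(t_frames)
  ctx$capture <- capture
  out <- forward_node(model$graph, character(0), x, model, ctx)
  list(out = out, ctx = ctx)
}

## backward ---------------------------------------------------------------

acc_grad <- function(pe, field, g) {
  gf <- paste0("grad_", field)
  if (is.null(pe[[gf]])) pe[[gf]] <- g else pe[[gf]] <- pe[[gf]] + g
}

backward_node <- function(node, path, dy, model, ctx) {
  key <- paste(path, collapse = ".")
  if (node$kind != "block" && identical(ctx$capture, key))
    ctx$capture_grad <- dy
  switch(node$kind,
    seq = {
      for (nm in rev(names(node$children)))
        dy <- backward_node(node$children[[nm]], c(path, nm), dy, model, ctx)
      dy
    },
    pool = {
      d <- ctx$caches[[key]]
      avgpool_bwd(dy, d[1], d[2], d[3], d[4], node$k, node$stride)
    },
    conv = {
      pe <- get(key, envir = model$params)
      cc <- ctx$caches[[key]]
      dmat <- aperm(dy, c(3, 1, 2, 4))
      dim(dmat) <- c(node$out_ch, length(dmat) %/% node$out_ch)
      acc_grad(pe, "W", tcrossprod(dmat, cc$cols))
      if (node$bias) acc_grad(pe, "b", rowSums(dmat))
      dcols <- crossprod(pe$W, dmat)
      d <- cc$dims
      col2im_hwcn(dcols, d[1], d[2], d[3], d[4], node$k, node$k,
                  node$stride, node$pad)
    },
    norm = {
      pe <- get(key, envir = model$params)
      cc <- ctx$caches[[key]]
      d <- cc$d
      m <- prod(d[c(1, 2, 4)])
      dym <- matrix(aperm(dy, c(1, 2, 4, 3)), m, d[3])
      acc_grad(pe, "gamma", colSums(dym * cc$xhat))
      acc_grad(pe, "beta", colSums(dym))
      dxhat <- dym * rep(pe$gamma, each = m)
      if (isTRUE(cc$batch)) {
        s1 <- colSums(dxhat)
        s2 <- colSums(dxhat * cc$xhat)
        dxm <- (dxhat - rep(s1 / m, each = m) -
                  cc$xhat * rep(s2 / m, each = m)) * rep(cc$invstd, each = m)
      } else {
        dxm <- dxhat * rep(cc$invstd, each = m)  # frozen running stats
      }
      dim(dxm) <- d[c(1, 2, 4, 3)]
      aperm(dxm, c(1, 2, 4, 3))
    },
    act = dy * ctx$caches[[key]],
    gap = {
      d <- ctx$caches[[key]]
      hw <- d[1] * d[2]
      dx <- array(rep(as.numeric(dy) / hw, each = hw), dim = d)
      dx
    },
    linear = {
      pe <- get(key, envir = model$params)
      xin <- ctx$caches[[key]]
      acc_grad(pe, "W", tcrossprod(dy, xin))
      if (node$bias) acc_grad(pe, "b", rowSums(dy))
      crossprod(pe$W, dy)
    },
    tsm = tsm_shift_hwcn(dy, ctx$t_frames, model$shift, -1L),
    block = {
      if (!is.null(node$post)) {
        pkey <- paste(c(path, "relu3"), collapse = ".")
        if (identical(ctx$capture, pkey)) ctx$capture_grad <- dy
        dy <- dy * ctx$caches[[pkey]]
      }
      dbranch <- backward_node(node$branch, path, dy, model, ctx)
      dbranch + dy
    },
    stop("no backward for layer kind '", node$kind, "'"))
}

backward_model <- function(model, fw, dy) {
  dx <- backward_node(model$graph, character(0), dy, model, fw$ctx)
  invisible(dx)
}

zero_grads <- function(model) {
  for (nm in ls(model$params)) {
    pe <- get(nm, envir = model$params)
    for (gf in grep("^grad_", ls(pe), value = TRUE)) pe[[gf]] <- NULL
  }
}

grad_fields <- function(leaf_kind) {
  switch(leaf_kind, conv = c("W", "b"), linear = c("W", "b"),
         norm = c("gamma", "beta"), layer_scale = "gamma", character(0))
}

# global L2 norm over every accumulated gradient
global_grad_norm <- function(model) {
  ss <- 0
  for (nm in ls(model$params)) {
    pe <- get(nm, envir = model$params)
    for (gf in grep("^grad_", ls(pe), value = TRUE))
      ss <- ss + sum(pe[[gf]]^2)
  }
  sqrt(ss)
}

#' Clip gradients to a maximum L2 norm
#'
#' Rescales the concatenated gradient vector of all trainable tensors so
#' its global L2 norm is at most `max_norm` (a no-op when already
#' within). Applied once per optimization step before the weight-decay
#' term is added.
#'
#' @param model model with accumulated gradients.
#' @param max_norm positive clipping threshold.
#' @return the pre-clipping global norm, invisibly.
#' @export
clip_gradients <- function(model, max_norm) {
  nrm <- global_grad_norm(model)
  if (is.finite(nrm) && nrm > max_norm) {
    sc <- max_norm / nrm
    for (nm in ls(model$params)) {
      pe <- get(nm, envir = model$params)
      for (gf in grep("^grad_", ls(pe), value = TRUE))
        pe[[gf]] <- pe[[gf]] * sc
    }
  }
  invisible(nrm)
}

# SGD with momentum: v <- momentum * v + (g + wd * theta); theta <- theta
# - lr * v  (gradient already clipped; decay applied to every trainable
# tensor, as in the conventional coupled-L2 formulation).
sgd_step <- function(model, cfg) {
  leaves <- param_leaf_paths(model)
  for (nm in names(leaves)) {
    pe <- get(nm, envir = model$params)
    for (f in grad_fields(leaves[[nm]]$kind)) {
      if (is.null(pe[[f]]) || is.null(pe[[paste0("grad_", f)]])) next
      g <- pe[[paste0("grad_", f)]] + cfg$weight_decay * pe[[f]]
      vf <- paste0("v", f)
      if (is.null(pe[[vf]])) pe[[vf]] <- 0 * g
      pe[[vf]] <- cfg$momentum * pe[[vf]] + g
      pe[[f]] <- pe[[f]] - cfg$lr * pe[[vf]]
    }
  }
  invisible(model)
}

# deep-copy / restore trainable state (best-checkpoint bookkeeping)
snapshot_params <- function(model) {
  out <- list()
  for (nm in ls(model$params))
    out[[nm]] <- as.list(get(nm, envir = model$params))
  out
}

restore_params <- function(model, snap) {
  params <- new.env(parent = emptyenv())
  for (nm in names(snap))
    assign(nm, list2env(snap[[nm]], parent = emptyenv()), envir = params)
  model$params <- params
  model
}

# Split a leading parameter-free average-pooling layer off the graph so
# its (gradient-free, deterministic) output can be memoized per clip
# across epochs; returns the trimmed model and the prefix function.
split_free_prefix <- function(model) {
  g <- model$graph
  if (g$kind == "seq" && length(g$children) > 0L) {
    first <- g$children[[1L]]
    if (first$kind == "seq" && length(first$children) > 0L &&
        first$children[[1L]]$kind == "pool" &&
        first$children[[1L]]$pool == "avg") {
      node <- first$children[[1L]]
      g$children[[1L]]$children[[1L]] <- NULL
      model$graph <- g
      pre <- function(arr) {
        d <- dim(arr)
        avgpool_fwd(arr, d[1L], d[2L], d[3L], d[4L], node$k, node$stride)
      }
      return(list(model = model, pre = pre))
    }
  }
  list(model = model, pre = identity)
}

# clip batch -> engine layout (H, W, C, B*T)
clips_to_batch <- function(clips) {
  d <- dim(clips[[1L]])
  tt <- d[1L]
  arrs <- lapply(clips, function(x) aperm(as_array(x), c(3L, 4L, 2L, 1L)))
  out <- array(0, dim = c(d[3L], d[4L], d[2L], tt * length(clips)))
  for (i in seq_along(arrs))
    out[, , , (i - 1L) * tt + seq_len(tt)] <- arrs[[i]]
  out
}

#' Frame-mean temporal consensus
#'
#' Aggregates per-frame class logits into one clip-level logit vector by
#' the arithmetic mean over frames. Deterministic; rejects empty input.
#'
#' @param per_frame_logits a `T x K` matrix (rows = frames).
#' @return numeric length-`K` clip logits.
#' @export
temporal_consensus_head <- function(per_frame_logits) {
  m <- as.matrix(per_frame_logits)
  if (nrow(m) == 0L) stop("no frames to aggregate")
  colMeans(m)
}

# frame logits (K, B*T) -> clip logits (K, B)
consensus_batch <- function(frame_logits, t_frames) {
  k <- nrow(frame_logits)
  b <- ncol(frame_logits) %/% t_frames
  dim(frame_logits) <- c(k, t_frames, b)
  out <- matrix(0, k, b)
  for (i in seq_len(b)) out[, i] <- rowMeans(frame_logits[, , i, drop = FALSE])
  out
}

softmax_xent <- function(clip_logits, labels01) {
  z <- sweep(clip_logits, 2, apply(clip_logits, 2, max))
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  idx <- cbind(labels01 + 1L, seq_along(labels01))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, grad = dlogits / length(labels01), prob = p)
}
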