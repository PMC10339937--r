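#' Shift configuration
#'
#' Governs the temporal shift operator. `shift_fraction` is the *total*
#' fraction of channels displaced in time, split evenly between the two
#' directions; with `C` channels, `floor(C * shift_fraction / 2)` channels
#' are shifted one frame forward and the same number one frame backward.
#' The default 1/4 keeps the bulk of each feature map frame-aligned so
#' spatial semantics are preserved while a quarter of the channels carry
#' neighboring-frame context. Vacated boundary frames are always filled
#' with exact zeros.
#'
#' @param shift_fraction total fraction of channels shifted, in `[0, 1]`.
#' @param fill boundary fill value; must be exactly 0 (the operator's
#'   contract), the argument exists so configurations are self-describing.
#' @return an object of class `"shift_config"`.
#' @examples
#' cfg <- shift_config()
#' shifted_channels(64, cfg)  # 8 forward + 8 backward = 16 of 64
#' @export
shift_config <- function(shift_fraction = 0.25, fill = 0) {
  if (!is.numeric(shift_fraction) || length(shift_fraction) != 1L ||
      !is.finite(shift_fraction) || shift_fraction < 0 || shift_fraction > 1)
    stop("shift_fraction must be a single number in [0, 1]")
  if (!identical(as.numeric(fill), 0))
    stop("boundary fill value must be exactly 0")
  structure(list(shift_fraction = shift_fraction,
                 per_direction_fraction = shift_fraction / 2,
                 fill = 0),
            class = "shift_config")
}

#' @rdname shift_config
#' @param n_channels channel count of the feature map.
#' @param cfg a `shift_config`.
#' @return `shifted_channels()` returns a list with the per-direction
#'   channel count `k` and the index sets of forward-, backward- and
#'   un-shifted channels (1-based).
#' @export
shifted_channels <- function(n_channels, cfg = shift_config()) {
  k <- floor(n_channels * cfg$shift_fraction / 2)
  list(k = k,
       forward  = if (k > 0) seq_len(k) else integer(0),
       backward = if (k > 0) k + seq_len(k) else integer(0),
       static   = if (2 * k < n_channels) (2 * k + 1):n_channels else integer(0))
}

#' Temporal shift operator
#'
#' Shifts a fixed fraction of a clip's channels one step along the frame
#' axis: the first `k = floor(C * f / 2)` channels move *forward in time*
#' (frame `t` receives frame `t-1`'s content, frame 1 is zero-filled), the
#' next `k` channels move backward (frame `t` receives frame `t+1`, the
#' last frame is zero-filled), and all remaining channels pass through
#' untouched. The operator holds no trainable state and never changes the
#' tensor shape; a 2D convolution applied after it mixes information
#' across adjacent frames, which is what gives a frame-wise 2D CNN
#' temporal modeling ability at zero parameter cost.
#'
#' Shifting is confined to one clip: batches must be shifted clip by clip
#' (the network layer threads the true frame count explicitly).
#'
#' @param x a [clip_tensor] `(T, C, H, W)`.
#' @param cfg a [shift_config].
#' @return a `clip_tensor` of identical shape.
#' @examples
#' x <- clip_tensor(array(rnorm(3 * 8 * 4 * 4), dim = c(3, 8, 4, 4)))
#' y <- temporal_shift(x, shift_config(0.5))
#' all(y[2, 1, , ] == x[1, 1, , ])  # channel 1 carries the previous frame
#' @export
temporal_shift <- function(x, cfg = shift_config()) {
  x <- clip_tensor(x)
  d <- dim(x)
  tt <- d[1L]; cc <- d[2L]
  ch <- shifted_channels(cc, cfg)
  out <- as_array(x)
  if (ch$k > 0) {
    xa <- as_array(x)
    out[, ch$forward, , ] <- 0
    out[, ch$backward, , ] <- 0
    if (tt > 1) {
      out[2:tt, ch$forward, , ] <- xa[1:(tt - 1), ch$forward, , , drop = FALSE]
      out[1:(tt - 1), ch$backward, , ] <- xa[2:tt, ch$backward, , , drop = FALSE]
    }
  }
  clip_tensor(out)
}

#' Shift/multiply-accumulate decomposition of a kernel-3 convolution
#'
#' A 1-D convolution `Y_i = w1 X_{i-1} + w2 X_i + w3 X_{i+1}` factors into
#' two steps: build the three shifted views `X^{-1}, X^0, X^{+1}` of the
#' signal (a free data movement), then multiply-accumulate them with the
#' kernel weights. This is the arithmetic identity behind the temporal
#' shift module: the shift costs nothing, and the multiply-accumulate is
#' absorbed into the next (2D) convolution. Out-of-range neighbors are
#' treated as zero.
#'
#' @param x numeric vector, the signal (non-empty, finite).
#' @param w numeric length-3 vector `(w1, w2, w3)` of kernel weights.
#' @return numeric vector `Y` of `length(x)`.
#' @examples
#' shift_decompose_conv(c(5, 7, 9), c(0, 1, 0))  # identity kernel
#' @export
shift_decompose_conv <- function(x, w) {
  if (length(x) < 1L) stop("signal must be non-empty")
  if (!all(is.finite(x))) stop("signal must be finite")
  if (length(w) != 3L || !all(is.finite(w))) stop("w must be 3 finite weights")
  # step 1: shifted views (X^{-1}, X^{0}, X^{+1}), zero at the boundaries
  x_m1 <- c(0, head(x, -1L))
  x_0  <- x
  x_p1 <- c(tail(x, -1L), 0)
  # step 2: multiply-accumulate
  w[1L] * x_m1 + w[2L] * x_0 + w[3L] * x_p1
}

#' Wrap a residual branch with a temporal shift
#'
#' Residual-style insertion: the shift is applied only on the
#' transformation (residual-mapping) branch, while the identity path
#' passes every frame through unmodified, so the original per-frame
#' content still reaches deeper layers intact. Returns the function
#' `x -> x + block_fn(temporal_shift(x, cfg))`.
#'
#' @param block_fn a function mapping a `clip_tensor` to a `clip_tensor`
#'   of the same shape (the block's transformation branch).
#' @param cfg a [shift_config].
#' @return a function with the same signature as `block_fn`.
#' @export
wrap_residual_branch <- function(block_fn, cfg = shift_config()) {
  stopifnot(is.function(block_fn))
  force(block_fn); force(cfg)
  function(x) {
    x <- clip_tensor(x)
    branch <- block_fn(temporal_shift(x, cfg))
    if (!identical(dim(branch), dim(x)))
      stop("residual branch output shape does not match identity path")
    clip_tensor(as_array(x) + as_array(branch))
  }
}

# Batched shift on engine-layout activations (H, W, C, N) where the N
# frames are clip-major (frames 1..T of clip 1, then clip 2, ...).
# direction = +1 applies the shift, -1 its adjoint (used in backprop:
# the transpose of "receive from t-1" is "send to t+1").
tsm_shift_hwcn <- function(x, t_frames, cfg, direction = 1L) {
  d <- dim(x)
  stopifnot(length(d) == 4L, d[4L] %% t_frames == 0L)
  cc <- d[3L]
  ch <- shifted_channels(cc, cfg)
  if (ch$k == 0L) return(x)
  n <- d[4L]
  tpos <- (seq_len(n) - 1L) %% t_frames          # 0-based frame index
  out <- x
  fwd <- if (direction > 0) ch$forward else ch$backward
  bwd <- if (direction > 0) ch$backward else ch$forward
  # forward shift: frame t takes frame t-1; first frame zero
  dst <- which(tpos > 0L)
  out[, , fwd, ] <- 0
  if (length(dst))
    out[, , fwd, dst] <- x[, , fwd, dst - 1L, drop = FALSE]
  # backward shift: frame t takes frame t+1; last frame zero
  dst <- which(tpos < t_frames - 1L)
  out[, , bwd, ] <- 0
  if (length(dst))
    out[, , bwd, dst] <- x[, , bwd, dst + 1L, drop = FALSE]
  out
}
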