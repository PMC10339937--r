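#' Clip tensors
#'
#' A decoded video clip is represented as a dense numeric array with
#' dimensions `(T, C, H, W)`: frame index, feature/color channel, row,
#' column. All values must be finite. This is the common currency between
#' the decoder, the synthetic generator, the shift operator and the
#' models.
#'
#' @param data numeric array with `dim` of length 4, `(T, C, H, W)`.
#' @return `clip_tensor()` returns its argument with class
#'   `"clip_tensor"` after validation.
#' @examples
#' x <- clip_tensor(array(0, dim = c(4, 3, 8, 8)))
#' n_frames(x)
#' @export
clip_tensor <- function(data) {
  if (!is.numeric(data) || length(dim(data)) != 4L)
    stop("clip tensor must be a numeric 4-d array (T, C, H, W)")
  if (any(dim(data) < 1L))
    stop("all clip tensor dimensions must be >= 1")
  if (!all(is.finite(data)))
    stop("clip tensor contains non-finite values")
  structure(data, class = "clip_tensor")
}

#' @rdname clip_tensor
#' @param x a `clip_tensor`.
#' @export
n_frames <- function(x) dim(x)[1L]

#' @rdname clip_tensor
#' @export
n_channels <- function(x) dim(x)[2L]

#' @export
print.clip_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<clip_tensor> T=%d frames, C=%d channels, %dx%d px, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], d[4], min(x), max(x)))
  invisible(x)
}

# strip the class for plain array arithmetic
as_array <- function(x) {
  attr(x, "class") <- NULL
  x
}
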