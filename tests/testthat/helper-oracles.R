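# Independent reference computations used across tests.

# brute-force zero-padded kernel-3 cross-correlation (the decomposition
# oracle): direct index arithmetic, no shifted views
brute_conv3 <- function(x, w) {
  n <- length(x)
  at <- function(i) if (i >= 1 && i <= n) x[i] else 0
  vapply(seq_len(n),
         function(i) w[1] * at(i - 1) + w[2] * at(i) + w[3] * at(i + 1),
         numeric(1))
}

# explicit index-remapping reference for the shift operator
brute_temporal_shift <- function(x, f) {
  d <- dim(x)
  tt <- d[1]; cc <- d[2]
  k <- floor(cc * f / 2)
  out <- array(0, dim = d)
  for (t in seq_len(tt)) for (c in seq_len(cc)) {
    src <- if (k > 0 && c <= k) t - 1            # forward in time
           else if (k > 0 && c <= 2 * k) t + 1   # backward in time
           else t
    if (src >= 1 && src <= tt) out[t, c, , ] <- x[src, c, , ]
  }
  out
}

rev_clip <- function(x) {
  a <- unclass(x)
  clip_tensor(a[rev(seq_len(dim(a)[1])), , , , drop = FALSE])
}

# swap the forward- and backward-shifted channel blocks
swap_shift_blocks <- function(x, f) {
  a <- unclass(x)
  k <- floor(dim(a)[2] * f / 2)
  if (k > 0) {
    perm <- seq_len(dim(a)[2])
    perm[1:k] <- k + 1:k
    perm[k + 1:k] <- 1:k
    a <- a[, perm, , , drop = FALSE]
  }
  clip_tensor(a)
}

random_clip <- function(tt, cc, h = 4, w = 4) {
  clip_tensor(array(rnorm(tt * cc * h * w), dim = c(tt, cc, h, w)))
}

# small scene for fast pipeline tests
small_scene <- function(seed = 1L, ...) {
  scene_params(frame_size = c(48L, 48L), blob_radius = 6, seed = seed, ...)
}
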