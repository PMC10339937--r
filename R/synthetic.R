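#' Synthetic scene parameters
#'
#' Controls the toy clip generator. Clips emulate the statistical
#' structure of overhead pen recordings at desk scale: bright
#' anti-aliased discs ("agents") moving on a dark background. The class
#' signal lives in displacement statistics, not in single-frame
#' appearance — an aggressive-proxy clip shows two agents converging,
#' making contact and then exhibiting coupled high-amplitude
#' displacement, while a calm clip shows independent slow drift. Defaults
#' render 1-s, 25-fps, 112x112 grayscale clips: agents span about a fifth
#' of the frame, aggressive displacement is a few pixels per frame
#' (roughly a body radius per 3 frames) versus sub-pixel calm drift, and
#' the additive pixel noise is small relative to the disc/background
#' contrast.
#'
#' @param frame_size `c(H, W)` in pixels.
#' @param n_agents rendered discs (>= 1; aggression uses the first two).
#' @param blob_radius disc radius, pixels.
#' @param fps frames per second.
#' @param duration_s clip duration, seconds.
#' @param speed_calm `c(mean, sd)` per-frame displacement, pixels/frame,
#'   calm clips.
#' @param speed_aggressive `c(mean, sd)` per-frame displacement during
#'   the convergence phase of aggressive clips.
#' @param contact_jitter amplitude (pixels) of the coupled oscillation
#'   after contact.
#' @param noise_sd additive Gaussian pixel noise (clip range is [0,1]).
#' @param seed RNG seed; fixes the full pixel output.
#' @return an object of class `"scene_params"`.
#' @export
scene_params <- function(frame_size = c(112L, 112L), n_agents = 2L,
                         blob_radius = 12, fps = 25L, duration_s = 1,
                         speed_calm = c(mean = 0.8, sd = 0.3),
                         speed_aggressive = c(mean = 4, sd = 1),
                         contact_jitter = 3, noise_sd = 0.02, seed = 1L) {
  p <- list(frame_size = as.integer(frame_size), n_agents = as.integer(n_agents),
            blob_radius = blob_radius, fps = as.integer(fps),
            duration_s = duration_s, speed_calm = speed_calm,
            speed_aggressive = speed_aggressive,
            contact_jitter = contact_jitter, noise_sd = noise_sd,
            seed = as.integer(seed))
  stopifnot(all(p$frame_size >= 8L), p$n_agents >= 1L, p$blob_radius > 0,
            p$fps >= 1L, p$duration_s > 0, p$noise_sd >= 0,
            speed_aggressive[["mean"]] > speed_calm[["mean"]])
  if (2 * p$blob_radius + 2 > min(p$frame_size))
    stop("agents cannot fit in the frame")
  structure(p, class = "scene_params")
}

# Render one grayscale frame: anti-aliased discs (coverage ramp of one
# pixel at the rim) on a dark background, combined by max. Coverage is
# evaluated only inside each disc's bounding box.
render_frame <- function(centers, p, intensities) {
  h <- p$frame_size[1L]; w <- p$frame_size[2L]
  img <- matrix(0.08, h, w)
  r <- p$blob_radius
  for (a in seq_len(nrow(centers))) {
    cy <- centers[a, 1L]; cx <- centers[a, 2L]
    ry <- max(1L, floor(cy - r - 1)):min(h, ceiling(cy + r + 1))
    rx <- max(1L, floor(cx - r - 1)):min(w, ceiling(cx + r + 1))
    d <- sqrt(outer((ry - cy)^2, (rx - cx)^2, "+"))
    cov <- pmin(pmax(r + 0.5 - d, 0), 1)
    img[ry, rx] <- pmax(img[ry, rx], cov * intensities[a])
  }
  img
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

reflect_into <- function(v, lo, hi) {
  # reflect a coordinate back into [lo, hi]
  if (v < lo) v <- lo + (lo - v)
  if (v > hi) v <- hi - (v - hi)
  min(max(v, lo), hi)
}

#' Generate a labeled synthetic clip
#'
#' Renders one clip of `fps * duration_s` frames. Label 1 (aggression
#' proxy): the first two agents converge at `speed_aggressive`, make
#' contact, and then oscillate jointly with amplitude `contact_jitter`
#' (coordinated multi-agent displacement). Label 0 (calm): each agent
#' drifts independently at `speed_calm` with a slowly wandering heading.
#' Output is a pure function of `(label, p)` — the RNG is scoped to
#' `p$seed` and the caller's RNG state is untouched.
#'
#' @param label 0 or 1.
#' @param p a [scene_params].
#' @return a [clip_tensor] of shape `(T, 1, H, W)` with values in [0,1].
#' @export
generate_clip <- function(label, p = scene_params()) {
  stopifnot(label %in% c(0L, 1L))
  restore <- local_rng(p$seed + 7L * label)
  on.exit(restore(), add = TRUE)
  n_t <- as.integer(round(p$fps * p$duration_s))
  h <- p$frame_size[1L]; w <- p$frame_size[2L]
  r <- p$blob_radius
  lo <- r + 1; hi_y <- h - r; hi_x <- w - r
  n_a <- p$n_agents
  intensities <- seq(0.85, 0.6, length.out = n_a)
  pos <- cbind(runif(n_a, lo, hi_y), runif(n_a, lo, hi_x))
  if (label == 1L && n_a >= 2L) {
    # start the pair well apart so convergence is visible
    pos[1L, ] <- c(runif(1, lo, hi_y), runif(1, lo, lo + (hi_x - lo) * 0.25))
    pos[2L, ] <- c(runif(1, lo, hi_y), runif(1, hi_x - (hi_x - lo) * 0.25, hi_x))
  }
  heading <- runif(n_a, 0, 2 * pi)
  phase <- runif(1, 0, 2 * pi)
  frames <- array(0, dim = c(n_t, 1L, h, w))
  contact <- FALSE
  for (t in seq_len(n_t)) {
    frames[t, 1L, , ] <- render_frame(pos, p, intensities)
    if (label == 0L) {
      for (a in seq_len(n_a)) {
        sp <- max(rnorm(1, p$speed_calm[["mean"]], p$speed_calm[["sd"]]), 0)
        heading[a] <- heading[a] + rnorm(1, 0, 0.25)
        pos[a, ] <- pos[a, ] + sp * c(sin(heading[a]), cos(heading[a]))
        pos[a, 1L] <- reflect_into(pos[a, 1L], lo, hi_y)
        pos[a, 2L] <- reflect_into(pos[a, 2L], lo, hi_x)
      }
    } else {
      gap <- pos[2L, ] - pos[1L, ]
      dist <- sqrt(sum(gap^2))
      if (dist <= 2 * r) contact <- TRUE
      if (!contact) {
        sp <- max(rnorm(1, p$speed_aggressive[["mean"]],
                        p$speed_aggressive[["sd"]]), 0.5)
        step <- gap / max(dist, 1e-6) * sp
        pos[1L, ] <- pos[1L, ] + step
        pos[2L, ] <- pos[2L, ] - step
      } else {
        # coupled oscillation: shared rapid displacement of the pair plus
        # opposing push-pull along the contact axis
        phase <- phase + runif(1, 0.8, 1.6)
        common <- p$contact_jitter *
          c(sin(phase), cos(phase)) + rnorm(2, 0, 0.5)
        axis <- gap / max(dist, 1e-6)
        push <- p$contact_jitter * 0.6 * sin(2.2 * phase)
        pos[1L, ] <- pos[1L, ] + common + push * axis
        pos[2L, ] <- pos[2L, ] + common - push * axis
      }
      if (n_a > 2L) for (a in 3:n_a) {
        sp <- max(rnorm(1, p$speed_calm[["mean"]], p$speed_calm[["sd"]]), 0)
        heading[a] <- heading[a] + rnorm(1, 0, 0.25)
        pos[a, ] <- pos[a, ] + sp * c(sin(heading[a]), cos(heading[a]))
      }
      for (a in seq_len(n_a)) {
        pos[a, 1L] <- reflect_into(pos[a, 1L], lo, hi_y)
        pos[a, 2L] <- reflect_into(pos[a, 2L], lo, hi_x)
      }
    }
  }
  if (p$noise_sd > 0)
    frames <- frames + rnorm(length(frames), 0, p$noise_sd)
  clip_tensor(clamp01(frames))
}

direction_base_clip <- function(p, seed) {
  # one blob translating left-to-right at near-constant speed; seeded
  # vertical placement and small speed variation
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  n_t <- as.integer(round(p$fps * p$duration_s))
  h <- p$frame_size[1L]; w <- p$frame_size[2L]
  r <- p$blob_radius
  y <- runif(1, r + 1 + 0.1 * h, h - r - 0.1 * h)
  x0 <- r + 1
  x1 <- w - r
  speed_scale <- runif(1, 0.85, 1)
  xs <- x0 + (x1 - x0) * speed_scale * (seq_len(n_t) - 1) / (n_t - 1)
  frames <- array(0, dim = c(n_t, 1L, h, w))
  for (t in seq_len(n_t))
    frames[t, 1L, , ] <- render_frame(cbind(y, xs[t]), p, 0.85)
  if (p$noise_sd > 0)
    frames <- frames + rnorm(length(frames), 0, p$noise_sd)
  clip_tensor(clamp01(frames))
}

reverse_clip <- function(x) {
  x <- clip_tensor(x)
  clip_tensor(as_array(x)[rev(seq_len(dim(x)[1L])), , , , drop = FALSE])
}

#' Playback-direction task
#'
#' Generates `n` clips of a single blob translating left-to-right (label
#' 0) or right-to-left (label 1), where every label-1 clip is the *exact
#' frame reversal* of a label-0 clip (noise included). The two members of
#' a pair therefore contain the identical multiset of frames, so any
#' classifier whose prediction is invariant to frame order attains
#' exactly chance accuracy by construction — only a temporally aware
#' model can beat it. This isolates the capability the temporal shift
#' module adds.
#'
#' @param n even clip count (`n/2` reversed pairs).
#' @param p a [scene_params].
#' @param out_dir where to write frame directories; `NULL` keeps the
#'   rendered tensors in an in-memory store attached to the manifest
#'   (identical pixel content either way).
#' @return a [clip_manifest] of `n` records, `n/2` per class; paired rows
#'   are adjacent (base then reversal).
#' @export
generate_direction_task <- function(n, p = scene_params(), out_dir = NULL) {
  stopifnot(n >= 2L, n %% 2L == 0L)
  store <- list()
  recs <- vector("list", n)
  for (i in seq_len(n %/% 2L)) {
    base <- direction_base_clip(p, p$seed + 1000L + i)
    revd <- reverse_clip(base)
    p_lr <- sprintf("dir_%04d_lr", i)
    p_rl <- sprintf("dir_%04d_rl", i)
    if (!is.null(out_dir)) {
      write_clip_frames(base, file.path(out_dir, p_lr))
      write_clip_frames(revd, file.path(out_dir, p_rl))
      p_lr <- file.path(out_dir, p_lr); p_rl <- file.path(out_dir, p_rl)
    } else {
      store[[p_lr]] <- base; store[[p_rl]] <- revd
    }
    recs[[2L * i - 1L]] <- clip_record(p_lr, 0L, p$fps, p$duration_s)
    recs[[2L * i]] <- clip_record(p_rl, 1L, p$fps, p$duration_s)
  }
  m <- clip_manifest(do.call(rbind, recs))
  if (is.null(out_dir)) attr(m, "clip_store") <- store
  if (!is.null(out_dir))
    write_manifest(m, file.path(out_dir, "manifest.csv"))
  m
}

#' Balanced behavior dataset
#'
#' Generates `n_per_class` aggressive-proxy and `n_per_class` calm clips
#' (1 s at `p$fps` each, per-clip seeds derived from `p$seed`), mirroring
#' a balanced two-class clip dataset, and returns the manifest.
#'
#' @param n_per_class clips per class.
#' @param p a [scene_params].
#' @param out_dir frame-directory output root; `NULL` for the in-memory
#'   store.
#' @return a [clip_manifest] of `2 * n_per_class` records.
#' @export
generate_dataset <- function(n_per_class, p = scene_params(),
                             out_dir = NULL) {
  stopifnot(n_per_class >= 1L)
  store <- list()
  recs <- vector("list", 2L * n_per_class)
  k <- 0L
  for (lab in c(0L, 1L)) for (i in seq_len(n_per_class)) {
    k <- k + 1L
    pi <- p
    pi$seed <- p$seed + 10000L * lab + i
    x <- generate_clip(lab, pi)
    nm <- sprintf("clip_%s_%04d", c("calm", "aggr")[lab + 1L], i)
    if (!is.null(out_dir)) {
      write_clip_frames(x, file.path(out_dir, nm))
      nm <- file.path(out_dir, nm)
    } else store[[nm]] <- x
    recs[[k]] <- clip_record(nm, lab, p$fps, p$duration_s)
  }
  m <- clip_manifest(do.call(rbind, recs))
  if (is.null(out_dir)) attr(m, "clip_store") <- store
  if (!is.null(out_dir)) write_manifest(m, file.path(out_dir, "manifest.csv"))
  m
}
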