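#' Clip records and manifests
#'
#' A manifest is the label-bearing index of a clip dataset: one row per
#' clip with its location (a directory of numbered PNG frames), binary
#' behavior label (1 = aggressive proxy, 0 = calm), frame rate, duration
#' and split assignment. Paths must be unique.
#'
#' @param path clip locator (frame-image directory).
#' @param label integer 0/1.
#' @param fps frames per second (> 0).
#' @param duration_s clip duration in seconds (> 0).
#' @param split one of `"train"`, `"val"`, `"test"`, `"unassigned"`.
#' @return `clip_record()`: a one-row data frame; `clip_manifest()`: a
#'   validated manifest (class `"clip_manifest"`).
#' @export
clip_record <- function(path, label, fps = 25, duration_s = 1,
                        split = "unassigned") {
  stopifnot(length(path) == 1L, label %in% c(0L, 1L), fps > 0, duration_s > 0,
            split %in% c("train", "val", "test", "unassigned"))
  data.frame(path = as.character(path), label = as.integer(label),
             fps = as.numeric(fps), duration_s = as.numeric(duration_s),
             split = split, stringsAsFactors = FALSE)
}

#' @rdname clip_record
#' @param records a data frame of clip records (rows rbind-able from
#'   [clip_record()]).
#' @export
clip_manifest <- function(records) {
  req <- c("path", "label", "fps", "duration_s", "split")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop("manifest needs columns: ", paste(req, collapse = ", "))
  if (nrow(records) == 0L) stop("empty manifest")
  if (anyDuplicated(records$path))
    stop("duplicate clip paths in manifest")
  if (!all(records$label %in% c(0L, 1L)))
    stop("labels must be 0 (non-aggressive) or 1 (aggressive)")
  if (any(records$fps <= 0) || any(records$duration_s <= 0))
    stop("fps and duration_s must be positive")
  if (!all(records$split %in% c("train", "val", "test", "unassigned")))
    stop("unknown split value")
  records <- records[, req]
  class(records) <- c("clip_manifest", "data.frame")
  records
}

#' @rdname clip_record
#' @param m a `clip_manifest`.
#' @return `class_counts()`: named per-label clip totals.
#' @export
class_counts <- function(m) {
  c(non_aggressive = sum(m$label == 0L), aggressive = sum(m$label == 1L))
}

#' Frame sampling plan
#'
#' How a stored clip becomes a model input: how many frames are fed to
#' the network (`n_frames`, uniformly spaced over the decoded clip;
#' default all 25 frames of a 1-s 25-fps clip), and the spatial size
#' frames are rescaled to (`target_size = c(width, height)`, `NULL` to
#' keep the stored size). Decoded pixel values are in `[0, 1]`.
#'
#' @param n_frames frames fed to the model (>= 1).
#' @param target_size `c(width, height)` after rescale, or `NULL`.
#' @return an object of class `"sampling_plan"`.
#' @export
sampling_plan <- function(n_frames = 25L, target_size = c(720L, 480L)) {
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L) stop("n_frames must be >= 1")
  if (!is.null(target_size)) {
    target_size <- as.integer(target_size)
    if (length(target_size) != 2L || any(target_size < 1L))
      stop("target_size must be c(width, height)")
  }
  structure(list(n_frames = n_frames, target_size = target_size),
            class = "sampling_plan")
}

#' Uniform-interval frame sampling indices
#'
#' Picks `n_frames` indices uniformly spaced over `1..n_available`
#' (`floor` of a linearly spaced grid over the frame range). Indices are
#' strictly increasing and never duplicated when `n_frames <=
#' n_available`; asking for more frames than exist is an error — clips
#' are never padded.
#'
#' @param n_available decoded frame count.
#' @param n_frames frames to select.
#' @return integer vector of 1-based frame indices.
#' @export
sample_frame_indices <- function(n_available, n_frames) {
  if (n_frames > n_available)
    stop(sprintf("clip has %d frames, %d requested (no padding)",
                 n_available, n_frames))
  if (n_frames == 1L) return(1L)
  as.integer(floor(seq(0, n_available - 1, length.out = n_frames))) + 1L
}

read_frame_png <- function(f) {
  img <- png::readPNG(f)
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' Read a clip as a tensor
#'
#' Decodes a clip into a [clip_tensor]. Clips are stored as directories
#' of numbered PNG frames (the canonical on-disk format; one image per
#' frame, all the same size). Frames are sampled per the plan in stored
#' order, rescaled bilinearly to `target_size` when requested, and
#' returned with pixel values in `[0, 1]`. Reading the same directory
#' twice yields bit-identical tensors. Container video files (MP4/AVI)
#' are rejected: decode them to frame directories first.
#'
#' @param record a one-row clip record (or a list with `$path`).
#' @param plan a [sampling_plan].
#' @return a [clip_tensor] with exactly `plan$n_frames` frames.
#' @export
read_clip <- function(record, plan = sampling_plan(target_size = NULL)) {
  path <- record$path
  if (!dir.exists(path)) {
    if (file.exists(path))
      stop("'", path, "' is a file, not a frame directory; ",
           "decode video containers to per-frame PNG directories first")
    stop("clip path not found: ", path)
  }
  frames <- list.files(path, pattern = "\\.png$", full.names = TRUE)
  if (length(frames) == 0L) stop("no PNG frames in ", path)
  frames <- frames[order(frames)]
  idx <- sample_frame_indices(length(frames), plan$n_frames)
  imgs <- lapply(frames[idx], read_frame_png)
  d <- dim(imgs[[1L]])
  if (!all(vapply(imgs, function(i) identical(dim(i), d), logical(1))))
    stop("inconsistent frame sizes in ", path)
  if (!is.null(plan$target_size) &&
      !identical(c(d[2L], d[1L]), as.integer(plan$target_size))) {
    w <- plan$target_size[1L]; h <- plan$target_size[2L]
    imgs <- lapply(imgs, function(img) {
      out <- array(0, dim = c(h, w, d[3L]))
      for (c in seq_len(d[3L]))
        out[, , c] <- resize_bilinear(img[, , c], h, w)
      out
    })
    d <- dim(imgs[[1L]])
  }
  x <- array(0, dim = c(length(imgs), d[3L], d[1L], d[2L]))
  for (t in seq_along(imgs))
    x[t, , , ] <- aperm(imgs[[t]], c(3L, 1L, 2L))
  clip_tensor(x)
}

#' Write a clip as a PNG frame directory
#'
#' Inverse of [read_clip()] for 1- or 3-channel clips: frame `t` is
#' written as `frame_####.png` with values clamped to `[0, 1]`.
#'
#' @param x a [clip_tensor].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_clip_frames <- function(x, dir) {
  x <- clip_tensor(x)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(x)
  for (t in seq_len(d[1L])) {
    chw <- array(as_array(x)[t, , , ], dim = d[2:4])
    img <- pmin(pmax(aperm(chw, c(2L, 3L, 1L)), 0), 1)
    if (d[2L] == 1L) dim(img) <- dim(img)[1:2]
    png::writePNG(img, file.path(dir, sprintf("frame_%04d.png", t)))
  }
  invisible(dir)
}

#' Stratified 6:2:2 manifest split
#'
#' Assigns every record to train/val/test, stratified by label: within
#' each class, `floor(n * r / sum(ratio))` records go to each split and
#' any remainder goes to train. Assignment is a seeded random
#' permutation, so it is deterministic for a fixed seed and forms an
#' exact partition. With 5220 + 5220 records at 6:2:2 this yields
#' 6264 / 2088 / 2088.
#'
#' @param m a [clip_manifest] with all records unassigned.
#' @param ratio positive integer triple, train:val:test.
#' @param seed integer RNG seed for the permutation.
#' @param group optional character vector (same length as the manifest)
#'   of source-video identifiers; when given, all clips sharing a group
#'   stay in one split (groups are assigned by the same remainder rule on
#'   group counts).
#' @return the manifest with `split` filled in.
#' @export
split_manifest <- function(m, ratio = c(6L, 2L, 2L), seed = 1L,
                           group = NULL) {
  m <- clip_manifest(m)
  if (!all(m$split == "unassigned"))
    stop("manifest already has split assignments")
  ratio <- as.integer(ratio)
  if (length(ratio) != 3L || any(ratio <= 0L))
    stop("ratio must be three positive integers")
  assign_units <- function(n) {
    k <- floor(n * ratio / sum(ratio))
    k[1L] <- k[1L] + (n - sum(k))  # remainder to train
    rep(c("train", "val", "test"), times = k)
  }
  out <- m
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  for (lab in sort(unique(m$label))) {
    sel <- which(m$label == lab)
    if (is.null(group)) {
      perm <- sample(length(sel))
      out$split[sel[perm]] <- assign_units(length(sel))
    } else {
      g <- group[sel]
      ug <- unique(g)
      perm <- sample(length(ug))
      gsplit <- stats::setNames(assign_units(length(ug)), ug[perm])
      out$split[sel] <- unname(gsplit[g])
    }
  }
  out
}

#' Manifest CSV round-trip
#'
#' The manifest serialization format is a plain CSV with the fixed header
#' `path,label,fps,duration_s,split`. Round-trips are lossless; duplicate
#' paths, unknown labels and malformed files are rejected. LF and CRLF
#' line endings parse identically.
#'
#' @param m a [clip_manifest].
#' @param path CSV location.
#' @export
write_manifest <- function(m, path) {
  m <- clip_manifest(m)
  write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("path", "label", "fps", "duration_s", "split")
  if (!all(req %in% names(df)))
    stop("malformed manifest CSV (expected header ",
         paste(req, collapse = ","), ")")
  df$label <- as.integer(df$label)
  clip_manifest(df)
}

# Seeded RNG scope: returns a restore function for the caller's RNG state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

# In-memory clip store: manifests produced by the generators may carry
# the rendered tensors so training does not have to touch the disk.
clip_store <- function(m) attr(m, "clip_store")

fetch_clip <- function(m, i, plan) {
  store <- clip_store(m)
  p <- m$path[i]
  if (!is.null(store) && !is.null(store[[p]])) {
    x <- store[[p]]
    idx <- sample_frame_indices(dim(x)[1L], plan$n_frames)
    clip_tensor(as_array(x)[idx, , , , drop = FALSE])
  } else {
    read_clip(m[i, ], plan)
  }
}
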