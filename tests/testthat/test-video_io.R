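make_manifest <- function(n, labels = rep(0:1, length.out = n)) {
  clip_manifest(do.call(rbind, lapply(seq_len(n), function(i)
    clip_record(sprintf("clip_%03d", i), labels[i]))))
}

test_that("manifest CSV round-trips losslessly and rejects malformed input", {
  m <- make_manifest(6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, f)
  m2 <- read_manifest(f)
  expect_equal(as.data.frame(m), as.data.frame(m2))
  # duplicate paths rejected
  bad <- as.data.frame(m); bad$path[2] <- bad$path[1]
  expect_error(clip_manifest(bad), "duplicate")
  # unknown labels rejected
  bad <- as.data.frame(m); bad$label[1] <- 3L
  expect_error(clip_manifest(bad), "label")
  # malformed header rejected
  writeLines(c("a,b", "1,2"), f)
  expect_error(read_manifest(f), "malformed")
})

test_that("CRLF and LF manifest files parse identically", {
  m <- make_manifest(4)
  f_lf <- withr::local_tempfile(fileext = ".csv")
  f_crlf <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, f_lf)
  lines <- readLines(f_lf)
  con <- file(f_crlf, "wb")
  writeLines(lines, con, sep = "\r\n")
  close(con)
  expect_equal(as.data.frame(read_manifest(f_crlf)),
               as.data.frame(read_manifest(f_lf)))
})

test_that("6:2:2 split arithmetic matches the remainder rule", {
  # exact division
  s10 <- split_manifest(make_manifest(10, labels = rep(0L, 10)), seed = 1)
  expect_equal(as.integer(table(s10$split)[c("train", "val", "test")]),
               c(6L, 2L, 2L))
  # remainder goes to train
  s11 <- split_manifest(make_manifest(11, labels = rep(0L, 11)), seed = 1)
  expect_equal(sum(s11$split == "train"), 7L)
  expect_equal(sum(s11$split == "val"), 2L)
  expect_equal(sum(s11$split == "test"), 2L)
})

test_that("a balanced 10,440-clip manifest splits into 6264/2088/2088", {
  m <- make_manifest(10440, labels = rep(0:1, each = 5220))
  s <- split_manifest(m, c(6, 2, 2), seed = 42)
  expect_equal(sum(s$split == "train"), 6264L)
  expect_equal(sum(s$split == "val"), 2088L)
  expect_equal(sum(s$split == "test"), 2088L)
  # stratified: each class is itself 6:2:2
  for (lab in 0:1) {
    sl <- s$split[s$label == lab]
    expect_equal(sum(sl == "train"), 3132L)
    expect_equal(sum(sl == "val"), 1044L)
  }
  # partition, deterministic under the seed
  expect_true(all(s$split != "unassigned"))
  expect_identical(split_manifest(m, c(6, 2, 2), seed = 42)$split, s$split)
  expect_error(split_manifest(s, seed = 1), "already")
})

test_that("group-aware splitting keeps clips from one source video together", {
  m <- make_manifest(40, labels = rep(0:1, each = 20))
  grp <- paste0("src", rep(1:10, each = 4))
  s <- split_manifest(m, seed = 3, group = grp)
  for (g in unique(grp))
    expect_length(unique(s$split[grp == g]), 1L)
})

test_that("uniform frame sampling matches independent index arithmetic", {
  expect_identical(sample_frame_indices(25, 25), 1:25)
  # linspace oracle: floor((j-1) * (L-1) / (n-1)) + 1
  for (case in list(c(50, 25), c(100, 25), c(26, 8), c(7, 7))) {
    L <- case[1]; n <- case[2]
    oracle <- floor((seq_len(n) - 1) * (L - 1) / (n - 1)) + 1
    got <- sample_frame_indices(L, n)
    expect_identical(got, as.integer(oracle))
    expect_true(all(diff(got) > 0))       # strictly increasing, no dupes
    expect_true(all(got >= 1 & got <= L))
  }
  expect_error(sample_frame_indices(10, 25), "no padding")
})

test_that("frame-directory clips decode deterministically and in order", {
  dir <- withr::local_tempdir()
  # frame index encoded in intensity so order is observable
  x <- array(0, dim = c(25, 1, 16, 16))
  for (t in 1:25) x[t, 1, , ] <- t / 25
  write_clip_frames(clip_tensor(x), dir)
  plan <- sampling_plan(25, target_size = NULL)
  rec <- list(path = dir)
  y1 <- read_clip(rec, plan)
  expect_equal(dim(y1), c(25L, 1L, 16L, 16L))
  expect_equal(y1[, 1, 1, 1], round((1:25) / 25 * 255) / 255,
               tolerance = 1e-12)
  # bit-identical on re-read
  expect_identical(unclass(read_clip(rec, plan)), unclass(y1))
  # requesting more frames than stored is a hard error
  expect_error(read_clip(rec, sampling_plan(30, target_size = NULL)),
               "no padding")
  # video container files are rejected with guidance
  f <- file.path(dir, "..", "clip.mp4"); file.create(f)
  expect_error(read_clip(list(path = f), plan), "frame directory")
})

test_that("rescaling to the target size preserves shape contract", {
  dir <- withr::local_tempdir()
  set.seed(8)
  x <- array(runif(5 * 1 * 24 * 32), dim = c(5, 1, 24, 32))
  write_clip_frames(clip_tensor(x), dir)
  y <- read_clip(list(path = dir),
                 sampling_plan(5, target_size = c(16, 12)))  # (w, h)
  expect_equal(dim(y), c(5L, 1L, 12L, 16L))
  expect_true(all(y >= 0 & y <= 1))
})
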