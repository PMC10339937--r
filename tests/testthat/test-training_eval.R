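test_that("metric formulas match hand arithmetic on the confusion counts", {
  counts <- structure(list(TP = 50L, FP = 10L, TN = 40L, FN = 0L),
                      class = "confusion_counts")
  rep <- metrics_report(counts)
  expect_equal(round(rep$accuracy, 2), 90.00)
  expect_equal(round(rep$recall, 2), 100.00)
  expect_equal(round(rep$precision, 2), 83.33)
  expect_equal(round(rep$f1, 2), 90.91)
})

test_that("degenerate metric cases follow the zero-denominator rule", {
  all_right <- structure(list(TP = 5L, FP = 0L, TN = 5L, FN = 0L),
                         class = "confusion_counts")
  r <- metrics_report(all_right)
  expect_equal(c(r$accuracy, r$recall, r$precision, r$f1),
               c(100, 100, 100, 100))
  no_pos <- structure(list(TP = 0L, FP = 0L, TN = 5L, FN = 5L),
                      class = "confusion_counts")
  r <- metrics_report(no_pos)
  expect_equal(r$recall, 0)
  expect_equal(r$f1, 0)
})

test_that("accuracy and F1 identities hold on random confusion counts", {
  set.seed(13)
  for (i in 1:25) {
    pred <- sample(0:1, 40, replace = TRUE)
    act <- sample(0:1, 40, replace = TRUE)
    cc <- confusion_counts(pred, act)
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 40L)
    r <- metrics_report(cc)
    expect_equal(r$accuracy, 100 * mean(pred == act))
    if (r$recall + r$precision > 0)
      expect_equal(r$f1, 2 * r$recall * r$precision / (r$recall + r$precision))
  }
})

test_that("one SGD+momentum step matches the closed-form update", {
  # quadratic toy loss L = 0.5 * ||theta||^2 has gradient g = theta;
  # check v <- m v + (g + wd theta); theta <- theta - lr v
  leaf <- shiftclip:::nd_linear(2, 1, bias = FALSE)
  model <- structure(list(
    spec = list(family = "probe"),
    graph = shiftclip:::nd_seq(list(fc = leaf)),
    shift = NULL, params = NULL), class = "tsm_model")
  params <- new.env(); pe <- new.env()
  theta0 <- matrix(c(3, -2), 1, 2)
  v0 <- matrix(c(0.5, 0.1), 1, 2)
  pe$W <- theta0; pe$grad_W <- theta0; pe$vW <- v0
  assign("fc", pe, envir = params)
  model$params <- params
  cfg <- train_config(lr = 0.1, momentum = 0.9, weight_decay = 0.01)
  shiftclip:::sgd_step(model, cfg)
  v1 <- 0.9 * v0 + (theta0 + 0.01 * theta0)
  expect_equal(pe$vW, v1)
  expect_equal(pe$W, theta0 - 0.1 * v1)
})

test_that("gradient clipping rescales to the threshold exactly", {
  model <- structure(list(graph = NULL, params = new.env()),
                     class = "tsm_model")
  pe <- new.env(); pe$grad_W <- matrix(c(60, 80), 1)   # L2 norm 100
  assign("fc", pe, envir = model$params)
  pre <- clip_gradients(model, 40)
  expect_equal(pre, 100)
  expect_equal(sqrt(sum(pe$grad_W^2)), 40)
  expect_equal(pe$grad_W, matrix(c(24, 32), 1))
  # within the threshold: untouched
  pe$grad_W <- matrix(c(3, 4), 1)
  clip_gradients(model, 40)
  expect_equal(pe$grad_W, matrix(c(3, 4), 1))
})

make_tiny_task <- function(seed = 1L, n = 16L) {
  p <- small_scene(seed = seed)
  m <- generate_direction_task(n, p)
  m$split <- rep(c("train", "test"), times = c(n / 2, n / 2))
  tr <- m[m$split == "train", ]; te <- m[m$split == "test", ]
  attr(tr, "clip_store") <- attr(m, "clip_store")
  attr(te, "clip_store") <- attr(m, "clip_store")
  list(train = tr, test = te,
       plan = sampling_plan(25L, target_size = NULL))
}

test_that("zero learning rate leaves trainable parameters bit-identical", {
  tk <- make_tiny_task(31L)
  set.seed(2)
  net <- init_model_params(insert_tsm(build_toy_net(channels = 4L)))
  before <- shiftclip:::snapshot_params(net)
  fit <- train(net, tk$train, NULL,
               train_config(lr = 0, epochs = 1L, seed = 1L), tk$plan)
  after <- shiftclip:::snapshot_params(fit$model)
  for (nm in names(before))
    for (f in c("W", "b", "gamma", "beta"))
      if (!is.null(before[[nm]][[f]]))
        expect_identical(after[[nm]][[f]], before[[nm]][[f]])
})

test_that("training runs the recipe and gradients stay within the clip norm", {
  tk <- make_tiny_task(32L)
  set.seed(3)
  net <- init_model_params(insert_tsm(build_toy_net(channels = 4L)))
  cfg <- train_config(lr = 0.05, epochs = 2L, seed = 1L)
  fit <- train(net, tk$train, tk$test, cfg, tk$plan)
  expect_equal(nrow(fit$history), 2L)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(!is.na(fit$history$val_acc)))
  # clipping invariant on a sampled step: post-clip norm <= threshold
  b <- shiftclip:::batch_of(tk$train, 1:4, tk$plan)
  shiftclip:::zero_grads(fit$model)
  fw <- shiftclip:::forward_model(fit$model, b$x, b$t_frames, train = TRUE)
  ls <- shiftclip:::softmax_xent(
    shiftclip:::consensus_batch(fw$out, b$t_frames), b$labels)
  dframe <- ls$grad[, rep(1:4, each = b$t_frames), drop = FALSE] / b$t_frames
  shiftclip:::backward_model(fit$model, fw, dframe)
  clip_gradients(fit$model, cfg$grad_clip_max_norm)
  expect_lte(shiftclip:::global_grad_norm(fit$model),
             cfg$grad_clip_max_norm + 1e-9)
  expect_error(train(net, tk$train[0, ], NULL, cfg, tk$plan), "empty")
})

test_that("evaluation is deterministic and ties break to the negative class", {
  tk <- make_tiny_task(33L)
  set.seed(4)
  net <- init_model_params(insert_tsm(build_toy_net(channels = 4L)))
  e1 <- evaluate(net, tk$test, tk$plan)
  e2 <- evaluate(net, tk$test, tk$plan)
  expect_identical(e1$counts, e2$counts)
  total <- with(e1$counts, TP + FP + TN + FN)
  expect_equal(total, nrow(tk$test))
  # an untrained symmetric-logit model must not predict positive on ties:
  # force exact ties by zeroing the head
  pe <- get("head.fc", envir = net$params)
  pe$W[] <- 0; pe$b[] <- 0
  ez <- evaluate(net, tk$test, tk$plan)
  expect_equal(ez$counts$TP + ez$counts$FP, 0L)
})

test_that("checkpoints round-trip the model function", {
  tk <- make_tiny_task(34L, n = 8L)
  set.seed(5)
  net <- init_model_params(insert_tsm(build_toy_net(channels = 4L)))
  fit <- train(net, tk$train, NULL,
               train_config(lr = 0.05, epochs = 1L, seed = 1L), tk$plan)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$model, f)
  back <- load_checkpoint(f)
  expect_identical(evaluate(back, tk$test, tk$plan)$counts,
                   evaluate(fit$model, tk$test, tk$plan)$counts)
  expect_identical(back$shift$shift_fraction, 0.25)
})

test_that("consensus head averages frame logits", {
  expect_equal(temporal_consensus_head(rbind(c(2, 0), c(0, 2))), c(1, 1))
  one <- matrix(c(0.3, 0.7), 1)
  expect_equal(temporal_consensus_head(one[rep(1, 5), ]), c(0.3, 0.7))
  set.seed(3)
  m <- matrix(rnorm(10), 5, 2)
  expect_equal(temporal_consensus_head(m), colSums(m) / 5)
  expect_error(temporal_consensus_head(m[0, , drop = FALSE]), "frames")
})
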