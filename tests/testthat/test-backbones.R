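families <- c("resnet50", "resnext50", "convnext_t", "densenet201")

test_that("backbone parameter counts reproduce the published millions", {
  expect_equal(param_millions(count_parameters(
    build_backbone(backbone_spec("resnet50")))), 23.51)
  expect_equal(param_millions(count_parameters(
    build_backbone(backbone_spec("resnext50")))), 22.98)
  expect_equal(param_millions(count_parameters(
    build_backbone(backbone_spec("densenet201")))), 18.10)
})

test_that("convnext-tiny count matches an independent closed-form total", {
  # direct arithmetic over the published ConvNeXt-T layout, written out
  # independently of the graph builder
  dims <- c(96, 192, 384, 768); blocks <- c(3, 3, 9, 3)
  block_p <- function(d) {
    (d * 49 + d) +          # 7x7 depthwise conv + bias
      2 * d +               # layer norm
      (d * 4 * d + 4 * d) + # pointwise expand
      (4 * d * d + d) +     # pointwise project
      d                     # layer scale
  }
  total <- 3 * 96 * 16 + 96 + 2 * 96                   # stem conv + LN
  for (s in 1:4) {
    if (s > 1) total <- total + 2 * dims[s - 1] +
        dims[s - 1] * dims[s] * 4 + dims[s]            # downsample LN + 2x2 conv
    total <- total + blocks[s] * block_p(dims[s])
  }
  total <- total + 2 * 768 + 768 * 2 + 2               # final LN + 2-class head
  m <- build_backbone(backbone_spec("convnext_t"))
  expect_equal(count_parameters(m), total)
})

test_that("stage block counts are the family invariants", {
  expect_equal(backbone_spec("resnet50")$stage_blocks, c(3, 4, 6, 3))
  expect_equal(backbone_spec("resnext50")$stage_blocks, c(3, 4, 6, 3))
  expect_equal(backbone_spec("convnext_t")$stage_blocks, c(3, 3, 9, 3))
  expect_equal(backbone_spec("densenet201")$stage_blocks, c(6, 12, 48, 32))
  expect_error(backbone_spec("vgg16"))
  expect_error(backbone_spec("resnet50", num_classes = 1), "num_classes")
})

test_that("TSM insertion adds exactly zero parameters in every family", {
  for (fam in families) {
    m <- build_backbone(backbone_spec(fam))
    mt <- insert_tsm(m, shift_config())
    expect_identical(count_parameters(mt) - count_parameters(m), 0)
    expect_error(insert_tsm(mt), "double insertion")
  }
})

test_that("the shift is inserted before each block's first convolution", {
  m <- insert_tsm(build_backbone(backbone_spec("resnet50")))
  blk <- m$graph$children$stage2$children$block1$branch$children
  expect_equal(names(blk)[1:2], c("tsm", "conv1"))
  # DenseNet: pass-through concat features unshifted, shift just before
  # the 1x1 convolution inside the composite function
  d <- insert_tsm(build_backbone(backbone_spec("densenet201")))
  blk <- d$graph$children$stage2$children$block1$branch$children
  expect_equal(names(blk)[1:4], c("norm1", "relu1", "tsm", "conv1"))
  # ConvNeXt: before the 7x7 depthwise convolution
  cx <- insert_tsm(build_backbone(backbone_spec("convnext_t")))
  blk <- cx$graph$children$stage2$children$block1$branch$children
  expect_equal(names(blk)[1:2], c("tsm", "dwconv"))
})

test_that("layer registry resolves the Grad-CAM target stably in every family", {
  for (fam in families) {
    m1 <- build_backbone(backbone_spec(fam))
    m2 <- build_backbone(backbone_spec(fam))
    k1 <- gradcam_target(m1)
    expect_identical(k1, gradcam_target(m2))
    expect_true(k1 %in% layer_registry(m1))
    expect_match(k1, "^stage5\\.block")
  }
  expect_equal(gradcam_target(build_backbone(backbone_spec("resnext50"))),
               "stage5.block3.relu3")
})

test_that("parameter counting follows the layer formulas", {
  # 3x3 convolution, 2 -> 4 channels, with bias: 2*4*9 + 4 = 76
  expect_equal(shiftclip:::leaf_param_count(
    shiftclip:::nd_conv(3, 2, 4, bias = TRUE)), 76)
  expect_equal(shiftclip:::leaf_param_count(shiftclip:::nd_norm("bn", 32)), 64)
  # grouped convolution divides the input fan
  expect_equal(shiftclip:::leaf_param_count(
    shiftclip:::nd_conv(3, 32, 32, groups = 32)), 32 * 9)
  # frozen model counts zero trainable scalars
  m <- freeze_model(build_backbone(backbone_spec("resnet50")))
  expect_equal(count_parameters(m), 0)
})

test_that("toy net counts equal its materialized tensor sizes", {
  set.seed(9)
  net <- init_model_params(build_toy_net(channels = 6))
  total <- 0
  for (nm in ls(net$params)) {
    pe <- get(nm, envir = net$params)
    for (f in c("W", "b", "gamma", "beta"))
      if (!is.null(pe[[f]])) total <- total + length(pe[[f]])
  }
  # running stats are not trainable
  expect_equal(count_parameters(net), total)
  expect_identical(count_parameters(insert_tsm(net)), count_parameters(net))
})

test_that("zero shift fraction leaves the network function unchanged", {
  set.seed(11)
  x <- array(runif(16 * 16 * 1 * 6), dim = c(16, 16, 1, 6))
  set.seed(5); plain <- init_model_params(build_toy_net(
    channels = 4, entry_pool = 2, entry_stride = 1))
  set.seed(5); zshift <- init_model_params(insert_tsm(
    build_toy_net(channels = 4, entry_pool = 2, entry_stride = 1),
    shift_config(0)))
  fp <- shiftclip:::forward_model(plain, x, 3L, train = FALSE)
  fz <- shiftclip:::forward_model(zshift, x, 3L, train = FALSE)
  expect_identical(fp$out, fz$out)
  # with a nonzero fraction the function genuinely changes
  set.seed(5); wshift <- init_model_params(insert_tsm(
    build_toy_net(channels = 4, entry_pool = 2, entry_stride = 1),
    shift_config(0.5)))
  fw <- shiftclip:::forward_model(wshift, x, 3L, train = FALSE)
  expect_gt(max(abs(fw$out - fp$out)), 0)
})

test_that("an inserted block equals the hand-assembled shift-then-block composition", {
  set.seed(21)
  net <- init_model_params(insert_tsm(build_toy_net(
    channels = 4, n_blocks = 1, entry_pool = 1, entry_stride = 1)))
  tt <- 3L
  x <- array(runif(8 * 8 * 1 * tt), dim = c(8, 8, 1, tt))
  fw <- shiftclip:::forward_model(net, x, tt, train = FALSE,
                                  capture = "stage2.block1.relu3")
  engine_block_out <- fw$ctx$capture_act
  # manual composition: run the stem, then the branch as a *plain
  # sequence* sharing the same weights, add the identity, rectify
  stem <- net; stem$graph <- shiftclip:::nd_seq(
    list(stage1 = net$graph$children$stage1))
  x_mid <- shiftclip:::forward_model(stem, x, tt, train = FALSE)$out
  branch <- net; branch$graph <- shiftclip:::nd_seq(list(
    stage2 = shiftclip:::nd_seq(list(
      block1 = net$graph$children$stage2$children$block1$branch))))
  b_out <- shiftclip:::forward_model(branch, x_mid, tt, train = FALSE)$out
  manual <- pmax(b_out + x_mid, 0)
  expect_equal(engine_block_out, manual, tolerance = 1e-12)
})
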