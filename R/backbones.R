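#' Backbone specifications
#'
#' Describes one of the supported 2D CNN families. Per-stage block counts
#' are fixed properties of each family: (3,4,6,3) for ResNet50 and
#' ResNeXt50, (3,3,9,3) for ConvNeXt-tiny, (6,12,48,32) for DenseNet201
#' (stage 1 being the convolutional stem in all families). ResNeXt50 uses
#' the standard 32x4d configuration (cardinality 32, base width 4).
#'
#' @param family one of `"resnet50"`, `"resnext50"`, `"convnext_t"`,
#'   `"densenet201"`.
#' @param num_classes number of output classes (>= 2; default 2 for the
#'   aggressive / non-aggressive task).
#' @param cardinality,base_width group-convolution parameters, ResNeXt
#'   only.
#' @param growth_rate dense-layer output channels, DenseNet only.
#' @param pretrained logical flag recorded on the spec; externally
#'   supplied ImageNet-1K weights are an optional input, never computed
#'   here.
#' @return an object of class `"backbone_spec"`.
#' @export
backbone_spec <- function(family = c("resnet50", "resnext50", "convnext_t",
                                     "densenet201"),
                          num_classes = 2L, cardinality = 32L,
                          base_width = 4L, growth_rate = 32L,
                          pretrained = FALSE) {
  family <- match.arg(family)
  num_classes <- as.integer(num_classes)
  if (is.na(num_classes) || num_classes < 2L)
    stop("num_classes must be an integer >= 2")
  stage_blocks <- switch(family,
    resnet50    = c(3L, 4L, 6L, 3L),
    resnext50   = c(3L, 4L, 6L, 3L),
    convnext_t  = c(3L, 3L, 9L, 3L),
    densenet201 = c(6L, 12L, 48L, 32L))
  structure(list(family = family, stage_blocks = stage_blocks,
                 num_classes = num_classes,
                 cardinality = as.integer(cardinality),
                 base_width = as.integer(base_width),
                 growth_rate = as.integer(growth_rate),
                 pretrained = isTRUE(pretrained)),
            class = "backbone_spec")
}

## ---- layer-graph node constructors -------------------------------------

nd_seq <- function(children) list(kind = "seq", children = children)
nd_conv <- function(k, in_ch, out_ch, stride = 1L, pad = 0L, groups = 1L,
                    bias = FALSE)
  list(kind = "conv", k = as.integer(k), in_ch = as.integer(in_ch),
       out_ch = as.integer(out_ch), stride = as.integer(stride),
       pad = as.integer(pad), groups = as.integer(groups), bias = bias)
nd_norm <- function(type, c) list(kind = "norm", norm = type, c = as.integer(c))
nd_act <- function(fun) list(kind = "act", fun = fun)
nd_pool <- function(type, k, stride = k) list(kind = "pool", pool = type,
                                              k = as.integer(k),
                                              stride = as.integer(stride))
nd_gap <- function() list(kind = "gap")
nd_linear <- function(in_f, out_f, bias = TRUE)
  list(kind = "linear", in_f = as.integer(in_f), out_f = as.integer(out_f),
       bias = bias)
nd_scale <- function(c) list(kind = "layer_scale", c = as.integer(c))
nd_tsm <- function() list(kind = "tsm")
# A block: `branch` is the transformation path the shift is inserted into
# (at child position `insert_at`); `shortcut` NULL means identity,
# "concat" marks DenseNet-style feature reuse, a node is a projection.
nd_block <- function(branch, shortcut = NULL, post = NULL, insert_at = 1L,
                     style = "residual")
  list(kind = "block", branch = branch, shortcut = shortcut, post = post,
       insert_at = as.integer(insert_at), style = style)

## ---- family builders ----------------------------------------------------

bottleneck_block <- function(in_ch, planes, stride, groups, base_width) {
  width <- ((planes * base_width) %/% 64L) * groups
  out_ch <- planes * 4L
  branch <- nd_seq(list(
    conv1 = nd_conv(1, in_ch, width),
    bn1 = nd_norm("bn", width), relu1 = nd_act("relu"),
    conv2 = nd_conv(3, width, width, stride = stride, pad = 1, groups = groups),
    bn2 = nd_norm("bn", width), relu2 = nd_act("relu"),
    conv3 = nd_conv(1, width, out_ch),
    bn3 = nd_norm("bn", out_ch)))
  shortcut <- if (stride != 1L || in_ch != out_ch)
    nd_seq(list(conv = nd_conv(1, in_ch, out_ch, stride = stride),
                bn = nd_norm("bn", out_ch)))
  nd_block(branch, shortcut, post = nd_act("relu"), insert_at = 1L)
}

build_resnet_graph <- function(spec) {
  groups <- if (spec$family == "resnext50") spec$cardinality else 1L
  bw <- if (spec$family == "resnext50") spec$base_width else 64L
  stages <- list(stage1 = nd_seq(list(
    conv1 = nd_conv(7, 3, 64, stride = 2, pad = 3),
    bn1 = nd_norm("bn", 64), relu1 = nd_act("relu"),
    maxpool = nd_pool("max", 3, 2))))
  planes <- c(64L, 128L, 256L, 512L)
  in_ch <- 64L
  for (s in 1:4) {
    blocks <- list()
    for (b in seq_len(spec$stage_blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      blocks[[paste0("block", b)]] <-
        bottleneck_block(in_ch, planes[s], stride, groups, bw)
      in_ch <- planes[s] * 4L
    }
    stages[[paste0("stage", s + 1L)]] <- nd_seq(blocks)
  }
  stages$head <- nd_seq(list(
    gap = nd_gap(),
    fc = nd_linear(in_ch, spec$num_classes)))
  nd_seq(stages)
}

dense_layer <- function(in_ch, growth, bn_size = 4L) {
  branch <- nd_seq(list(
    norm1 = nd_norm("bn", in_ch), relu1 = nd_act("relu"),
    conv1 = nd_conv(1, in_ch, bn_size * growth),
    norm2 = nd_norm("bn", bn_size * growth), relu2 = nd_act("relu"),
    conv2 = nd_conv(3, bn_size * growth, growth, pad = 1)))
  # concatenation reuse: pass-through features are never shifted; the
  # shift sits just before the layer's first (1x1) convolution
  nd_block(branch, shortcut = "concat", insert_at = 3L, style = "dense")
}

build_densenet_graph <- function(spec) {
  growth <- spec$growth_rate
  stages <- list(stage1 = nd_seq(list(
    conv1 = nd_conv(7, 3, 64, stride = 2, pad = 3),
    bn1 = nd_norm("bn", 64), relu1 = nd_act("relu"),
    maxpool = nd_pool("max", 3, 2))))
  in_ch <- 64L
  for (s in 1:4) {
    blocks <- list()
    for (b in seq_len(spec$stage_blocks[s])) {
      blocks[[paste0("block", b)]] <- dense_layer(in_ch, growth)
      in_ch <- in_ch + growth
    }
    stages[[paste0("stage", s + 1L)]] <- nd_seq(blocks)
    if (s < 4L) {
      out_ch <- in_ch %/% 2L
      stages[[paste0("transition", s)]] <- nd_seq(list(
        norm = nd_norm("bn", in_ch), relu = nd_act("relu"),
        conv = nd_conv(1, in_ch, out_ch),
        pool = nd_pool("avg", 2)))
      in_ch <- out_ch
    }
  }
  stages$head <- nd_seq(list(
    norm_final = nd_norm("bn", in_ch),
    gap = nd_gap(),
    fc = nd_linear(in_ch, spec$num_classes)))
  nd_seq(stages)
}

convnext_block <- function(dim) {
  branch <- nd_seq(list(
    dwconv = nd_conv(7, dim, dim, pad = 3, groups = dim, bias = TRUE),
    ln = nd_norm("ln", dim),
    pwconv1 = nd_linear(dim, 4L * dim),
    gelu = nd_act("gelu"),
    pwconv2 = nd_linear(4L * dim, dim),
    gamma = nd_scale(dim)))
  nd_block(branch, insert_at = 1L, style = "convnext")
}

build_convnext_graph <- function(spec) {
  dims <- c(96L, 192L, 384L, 768L)
  stages <- list(stage1 = nd_seq(list(
    conv1 = nd_conv(4, 3, dims[1], stride = 4, bias = TRUE),
    ln1 = nd_norm("ln", dims[1]))))
  for (s in 1:4) {
    if (s > 1L)
      stages[[paste0("downsample", s - 1L)]] <- nd_seq(list(
        ln = nd_norm("ln", dims[s - 1L]),
        conv = nd_conv(2, dims[s - 1L], dims[s], stride = 2, bias = TRUE)))
    blocks <- list()
    for (b in seq_len(spec$stage_blocks[s]))
      blocks[[paste0("block", b)]] <- convnext_block(dims[s])
    stages[[paste0("stage", s + 1L)]] <- nd_seq(blocks)
  }
  stages$head <- nd_seq(list(
    gap = nd_gap(),
    ln_final = nd_norm("ln", dims[4]),
    fc = nd_linear(dims[4], spec$num_classes)))
  nd_seq(stages)
}

## ---- model handle -------------------------------------------------------

#' Build a backbone model
#'
#' Constructs the named architecture layer by layer as a structural graph
#' (every convolution, normalization, activation, pooling and linear
#' layer with its exact shape), with a `num_classes`-way classification
#' head. Parameter counts, TSM insertion points and the Grad-CAM layer
#' registry all derive from this graph, so counts are computed from the
#' architecture, never tabulated.
#'
#' @param spec a [backbone_spec].
#' @return an object of class `"tsm_model"`.
#' @examples
#' m <- build_backbone(backbone_spec("resnext50"))
#' param_millions(count_parameters(m))  # 22.98
#' @export
build_backbone <- function(spec) {
  if (!inherits(spec, "backbone_spec")) stop("spec must be a backbone_spec")
  graph <- switch(spec$family,
    resnet50 = , resnext50 = build_resnet_graph(spec),
    densenet201 = build_densenet_graph(spec),
    convnext_t = build_convnext_graph(spec))
  structure(list(spec = spec, graph = graph, shift = NULL, params = NULL),
            class = "tsm_model")
}

#' @export
print.tsm_model <- function(x, ...) {
  cat(sprintf("<tsm_model> family=%s classes=%d params=%s M%s\n",
              x$spec$family, x$spec$num_classes,
              format(param_millions(count_parameters(x)), nsmall = 2),
              if (is.null(x$shift)) "" else
                sprintf(" [TSM f=%g]", x$shift$shift_fraction)))
  invisible(x)
}

walk_leaves <- function(node, f, path = character(0)) {
  if (node$kind == "seq") {
    for (nm in names(node$children))
      walk_leaves(node$children[[nm]], f, c(path, nm))
  } else if (node$kind == "block") {
    walk_leaves(node$branch, f, path)
    if (is.list(node$shortcut)) walk_leaves(node$shortcut, f, c(path, "shortcut"))
    if (!is.null(node$post)) f(node$post, c(path, "relu3"))
  } else {
    f(node, path)
  }
  invisible(NULL)
}

leaf_param_count <- function(leaf) {
  if (isTRUE(leaf$frozen)) return(0)
  switch(leaf$kind,
    conv = leaf$out_ch * (leaf$in_ch %/% leaf$groups) * leaf$k * leaf$k +
      if (leaf$bias) leaf$out_ch else 0L,
    norm = 2L * leaf$c,
    linear = leaf$in_f * leaf$out_f + if (leaf$bias) leaf$out_f else 0L,
    layer_scale = leaf$c,
    0L)
}

#' Count trainable parameters
#'
#' Walks the model graph and sums the trainable scalars of every layer
#' (convolution kernels and biases, normalization scale/offset pairs,
#' linear weights, ConvNeXt layer-scale vectors). The temporal shift
#' module contributes nothing: it holds no trainable state, so a model's
#' count is invariant under TSM insertion.
#'
#' @param model a `"tsm_model"`.
#' @return exact integer-valued count of trainable scalars.
#' @seealso [param_millions()] for the conventional millions formatting.
#' @export
count_parameters <- function(model) {
  total <- 0
  walk_leaves(model$graph, function(leaf, path) {
    total <<- total + leaf_param_count(leaf)
  })
  total
}

#' @rdname count_parameters
#' @param n a parameter count.
#' @return `param_millions()`: the count in millions, rounded to 2 d.p.
#' @export
param_millions <- function(n) round(n / 1e6, 2)

#' @rdname count_parameters
#' @return `freeze_model()`: the model with every layer marked frozen
#'   (excluded from the trainable count and from optimizer updates).
#' @export
freeze_model <- function(model) {
  model$graph <- map_leaves(model$graph, function(leaf) {
    leaf$frozen <- TRUE
    leaf
  })
  model
}

map_leaves <- function(node, f) {
  if (node$kind == "seq") {
    node$children <- lapply(node$children, map_leaves, f = f)
  } else if (node$kind == "block") {
    node$branch <- map_leaves(node$branch, f)
    if (is.list(node$shortcut)) node$shortcut <- map_leaves(node$shortcut, f)
    if (!is.null(node$post)) node$post <- f(node$post)
  } else {
    node <- f(node)
  }
  node
}

## ---- TSM insertion ------------------------------------------------------

insert_tsm_node <- function(node) {
  if (node$kind == "seq") {
    node$children <- lapply(node$children, insert_tsm_node)
  } else if (node$kind == "block") {
    ch <- node$branch$children
    i <- node$insert_at
    node$branch$children <-
      append(ch, list(tsm = nd_tsm()), after = i - 1L)
    node$branch$children <- stats::setNames(
      node$branch$children,
      make.unique(names(node$branch$children)))
  }
  node
}

#' Insert temporal shift modules into a model
#'
#' Places a temporal shift in front of the first convolution of every
#' block's transformation branch, in all stages. Identity/skip paths (and
#' DenseNet's concatenated pass-through features) are never shifted, so
#' unmodified per-frame content still reaches deeper layers. The
#' operation adds exactly zero trainable parameters. The returned model
#' consumes clips with an explicit frame count `T`.
#'
#' @param model a `"tsm_model"` from [build_backbone()] or
#'   [build_toy_net()].
#' @param cfg a [shift_config].
#' @return the model with shift modules inserted; double insertion is an
#'   error.
#' @export
insert_tsm <- function(model, cfg = shift_config()) {
  if (!inherits(model, "tsm_model")) stop("not a tsm_model")
  if (!is.null(model$shift))
    stop("temporal shift modules already inserted; double insertion is not allowed")
  if (!inherits(cfg, "shift_config")) stop("cfg must be a shift_config")
  model$graph <- insert_tsm_node(model$graph)
  model$shift <- cfg
  model
}

## ---- layer registry / Grad-CAM target ----------------------------------

#' Layer registry and Grad-CAM target resolution
#'
#' `layer_registry()` lists the dotted path of every layer in the model
#' graph (e.g. `"stage5.block3.relu3"`). `gradcam_target()` resolves the
#' visualization target layer — the last activation of the third block of
#' the fifth stage — for each family, with the documented equivalents for
#' families whose blocks end differently: the post-addition ReLU for
#' ResNet50/ResNeXt50, the block's GELU for ConvNeXt-tiny, and the last
#' dense-layer activation of the final stage for DenseNet201.
#'
#' @param model a `"tsm_model"`.
#' @return `layer_registry()`: character vector of layer paths;
#'   `gradcam_target()`: a single path, guaranteed to be present in the
#'   registry.
#' @export
layer_registry <- function(model) {
  out <- character(0)
  walk_leaves(model$graph, function(leaf, path) {
    out <<- c(out, paste(path, collapse = "."))
  })
  out
}

#' @rdname layer_registry
#' @export
gradcam_target <- function(model) {
  key <- switch(model$spec$family,
    resnet50 = , resnext50 = "stage5.block3.relu3",
    convnext_t = "stage5.block3.gelu",
    densenet201 = sprintf("stage5.block%d.relu2",
                          tail(model$spec$stage_blocks, 1L)),
    toy_residual = {
      reg <- layer_registry(model)
      acts <- grep("relu", reg, value = TRUE)
      tail(acts, 1L)
    },
    stop("no Grad-CAM target rule for family ", model$spec$family))
  reg <- layer_registry(model)
  if (!key %in% reg)
    stop("Grad-CAM target layer '", key, "' not resolvable in this model")
  key
}
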