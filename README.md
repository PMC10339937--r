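# shiftclip

Temporal shift modules (TSM) for binary behavior classification of short
video clips, in R.

Recognizing aggressive interactions in group-housed animals from
overhead video — the motivating case is biting/knocking/treading/chasing
in pigs — requires temporal features: single frames rarely separate an
attack from benign contact, but coordinated multi-agent displacement
does. The temporal shift module gives an ordinary 2D CNN that capability
at **zero parameter and zero FLOP cost**: for a clip tensor with `T`
frames and `C` channels, a fraction `f` of the channels (default 1/4
total) is displaced one step along the frame axis — the first
`k = ⌊C·f/2⌋` channels forward in time, the next `k` backward, with
zero-filled boundaries — so the next 2D convolution mixes adjacent-frame
information. The underlying identity is the decomposition of a kernel-3
temporal convolution

```
Y_i = w1·X_{i−1} + w2·X_i + w3·X_{i+1}
```

into a free shift of the three views `X^{−1}, X^0, X^{+1}` followed by a
multiply-accumulate that is absorbed into the existing convolution.

The package provides, as a library plus a thin CLI:

- the shift operator, its decomposition, and residual-branch wrapping
  (`temporal_shift()`, `shift_decompose_conv()`,
  `wrap_residual_branch()`);
- structural builders for four backbone families — ResNet50, ResNeXt50
  (32×4d), ConvNeXt-tiny, DenseNet201 — with exact parameter accounting,
  TSM insertion before the first convolution of every block's
  transformation branch, and a Grad-CAM layer registry
  (`build_backbone()`, `insert_tsm()`, `count_parameters()`);
- clip ingestion from PNG frame directories, manifest CSVs, uniform
  frame sampling, and a stratified seeded 6:2:2 split
  (`read_clip()`, `split_manifest()`);
- a seeded synthetic-clip generator (aggression-proxy vs. calm motion,
  plus a playback-direction task whose classes are exact frame
  reversals of each other) so the whole pipeline runs with no external
  data (`generate_dataset()`, `generate_direction_task()`);
- an SGD+momentum training loop (lr 0.00125, momentum 0.9, weight decay
  1e-4, batch 8, global L2 gradient clipping at 40), confusion-count
  metrics (accuracy/recall/precision/F1), and per-frame Grad-CAM heatmap
  export with every-5th-frame display panels (`train()`, `evaluate()`,
  `gradcam_clip()`).

With a 2-class head the computed trainable-parameter counts are
23.51 M (ResNet50), 22.98 M (ResNeXt50), 18.10 M (DenseNet201) and
27.82 M (ConvNeXt-tiny), and TSM insertion changes none of them.

## Worked example

```r
library(shiftclip)

m  <- build_backbone(backbone_spec("resnext50", num_classes = 2))
mt <- insert_tsm(m, shift_config())      # shift 1/4 of channels, zero params
count_parameters(m)                      # 22984002  (22.98 M)
count_parameters(mt) - count_parameters(m)   # 0
gradcam_target(mt)                       # "stage5.block3.relu3"

# end-to-end on the synthetic playback-direction task
p   <- scene_params(seed = 7L)
man <- generate_direction_task(60L, p)   # 30 reversed pairs
man$split <- rep(c("train", "test"), c(40L, 20L))
tr <- man[man$split == "train", ]; te <- man[man$split == "test", ]
attr(tr, "clip_store") <- attr(man, "clip_store")
attr(te, "clip_store") <- attr(man, "clip_store")
plan <- sampling_plan(n_frames = 25L, target_size = NULL)

set.seed(7)
net <- init_model_params(insert_tsm(build_toy_net(), shift_config()))
fit <- train(net, tr, NULL, train_config(lr = 0.05, epochs = 8L, seed = 7L),
             plan)
evaluate(fit$model, te, plan)$metrics
```

which prints (epoch tail, then test metrics):

```
 epoch train_loss train_acc val_acc
     6  0.4577713        75      NA
     7  0.2422265       100      NA
     8  0.1459259       100      NA
accuracy 85.00%  recall 100.00%  precision 76.92%  F1 86.96%
```

The direction task is constructed so that a frame-order-invariant
classifier (the same net without TSM, using frame-mean consensus) sits
at exactly 50%: each label-1 clip is the exact frame reversal of a
label-0 clip, so both members of a pair receive identical consensus
logits. Even this 40-clip, 8-epoch run already separates the classes
well above chance; at the standard experiment scale (400 training
clips, 20 epochs, `temporal_discrimination_experiment()`) the TSM arm
reaches ≥ 90% while the baseline stays at 50%. Grad-CAM heatmaps
(`gradcam_clip()`) are produced one per frame, normalized to `[0, 1]`
per clip, with frames 1, 6, 11, 16, 21 of a 25-frame clip selected for
display panels.

A command-line wrapper is installed at `inst/cli/shiftclip.R`:

```sh
Rscript inst/cli/shiftclip.R params --family resnext50 --classes 2 --tsm
Rscript inst/cli/shiftclip.R generate --task direction --n 60 --out clips/
Rscript inst/cli/shiftclip.R experiment --seeds 3
```

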