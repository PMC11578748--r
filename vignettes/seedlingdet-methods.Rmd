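---
title: "Multi-scale seedling detection and counting: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale seedling detection and counting: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(seedlingdet)
```

## The problem

Counting crop seedlings from low-altitude UAV imagery is a small-object
detection problem under hostile conditions: plants a few dozen pixels across,
weeds whose blades look like seedling leaves, translucent plastic film that
partially occludes rows, and strong class imbalance (weeds are much rarer
than seedlings). `seedlingdet` implements a lightweight one-stage detector
specialized for this setting, the evaluation machinery around it, and a
reference-line counter that turns per-frame detections in fly-over video
into per-class field counts.

The package is deliberately self-contained: a small reverse-mode autodiff
engine (with compiled im2col convolution kernels) stands in for a deep
learning framework, and a procedural scene generator stands in for field
data, so that every architectural and algorithmic claim is testable on a
single CPU in minutes.

## The detector

The baseline topology is the familiar nano-scale one-stage design: a
stride-2 stem, four backbone stages of (stride-2 conv, C2f block) with
widths 16/32/64/128/256 and C2f repeats 1/2/2/1, spatial-pyramid pooling
(SPPF, kernel 5), a path-aggregation neck over the stride-8/16/32 levels,
and three decoupled anchor-free heads with a 16-bin discretized
box-distribution branch and a class branch. With two classes this assembles
to 3,011,222 learnable scalars, 3.0 M at the 0.1 M rounding used in ablation
tables — the fidelity oracle for every topology constant above.

Three independent modifications are provided, reproducing the ablation grid
`model0`–`model6` plus the full model:

**MSConv / MSBottleneck / MSModule.** MSConv splits its input into four
contiguous channel groups A–D. Groups A, B, C pass through 1×1, 3×3 and 5×5
conv cells (each `C/4 -> C/4`, conv–norm–SiLU); each processed group is then
rescaled per channel by a softmax attention over its own channels (descriptor
= global average pooling), so each group carries its own simplex. Group D is
concatenated untouched, and a 1×1 mixing cell (`C -> C`) exchanges channel
information. MSBottleneck is `x + MSConv(Conv3x3(x))`; MSModule is the C2f
block with every inner bottleneck replaced by MSBottleneck.

Two textual readings of the block were possible, and we let the printed
parameter sizes arbitrate. First, "concatenated with the original feature
map" could mean the untouched quarter (D) or the full input; the D-group
reading keeps the mixing conv at `C -> C` and matches the printed sizes, so
it is the default (the full-input reading would grow the mixing conv to
`7C/4 -> C`). Second, MSModule could replace C2f in the backbone only or
everywhere; replacing it in the backbone *and* the baseline neck's C2f blocks
yields 2,707,118 parameters (2.7 M) for the MSModule-only variant, exactly the
printed value, while backbone-only gives 2.86 M. The default is therefore
`msmodule_stages = "all"`; `"backbone"` and `"p4"` remain available.

**BiFPN-P2 neck.** Four backbone levels enter the neck: the first C2f output
(stride 4, the extra fine level for small objects) and the three standard
levels. Each passes a 1×1 lateral conv to a common width, then one top-down
sweep builds intermediates (each node fusing the level input with the
upsampled level above) and one bottom-up sweep builds outputs (fusing the
level input, the intermediate, and the downsampled level below). Fusion is
fast-normalized: per-input learnable scalars clamped at zero, coefficients
`w_i / (sum w + beta)` with `beta = 1e-4` (the convention of the original
fast-normalized fusion; the emulated study gives no value). Upsampling is
nearest-neighbour; downsampling is a learned stride-2 conv. Heads read the
three coarser fused levels (strides 8/16/32); the fine level participates in
fusion only.

The neck width is not stated in the source material; it is pinned by the
printed parameter sizes. With the canonical wiring above (6 fusion convs,
3 downsample convs, 4 lateral convs, 14 fusion scalars), width 60 gives
2,017,636 parameters (2.0 M) for the neck-only variant and 1,861,900 (1.9 M)
for the full model — both printed values — while width 64 would round to
2.1 M. `neck_width = 60` is therefore the default. A related arbitration: the
statement that "the P4 layer is obtained by MSModule" is read as describing
the backbone P4 stage (which uses MSModule whenever that flag is on), not as
an extra MSModule at the neck's P4 intermediate; at width 60 a C2f-style
block there is impossible (hidden width 30 is not divisible by 4) and a bare
MSConv there drops the full model to 1.8 M, off the printed value.

**MPDIoU box loss.** For corner-form boxes the loss is
`1 - [IoU - d1^2/(w^2+h^2) - d2^2/(w^2+h^2)]`, with `d1`, `d2` the distances
between the two boxes' top-left and bottom-right corners and `(w, h)` the
network input dimensions (losses are computed in network input space, after
letterboxing). It is symmetric, dominated by IoU, and bounded in `[0, 3]`
for boxes inside the image. The baseline CIoU loss is provided for the
unmodified variants, with the standard aspect term
`v = (4/pi^2)(atan(w_gt/h_gt) - atan(w_p/h_p))^2` and
`alpha = v/((1-IoU)+v)` treated as constant under differentiation.

## Training at desk scale

Training uses task-aligned assignment (candidates are anchors whose center
lies inside a ground-truth box; alignment `score^0.5 * IoU^6`, top-10 per
target, conflicts resolved by IoU; soft class targets normalized per target),
and the composite loss `7.5 * box + 0.5 * cls + 1.5 * dfl` — class BCE over
all anchors, distribution-focal cross-entropy over the box bins, and the
variant's geometric term. Gradients flow through the tape; the geometric
term is differentiated by central differences per assigned anchor (it is
closed-form scalar arithmetic, so this is cheap and exact to O(eps^2)) and
chained through the softmax-expectation decode analytically. The optimizer
is SGD with momentum 0.937, weight decay 5e-4 on conv weights, a 3-epoch
linear warmup into a cosine decay; the head's final biases are initialized
to the usual sparse-prior values, which matters for stable early training.

Class imbalance needs one extra ingredient at desk scale. With weeds four
times rarer than seedlings, the unweighted class BCE lets the detector find
weed tufts but label them as seedlings (error analysis on pilot runs showed
the large majority of seedling false positives sitting exactly on weed
objects). The standard remedy applies: the positive class-BCE terms are
weighted by inverse class frequency — `class_weights = c(1, 4)`, read
directly off the generator's designed 4:1 imbalance. Background terms keep
weight 1 so the rare class's negatives are not inflated.

Two profiles are built in. The `field` profile records the emulated study's
setup (batch 32, image size 1280, 300 epochs, nano widths) and is emitted
for documentation only. The `desk` profile is what the test suite exercises:
width multiplier 0.125 (stem 2, stages 4/8/16/32), 4 distribution bins,
image size 160, batch 8, 30 epochs, 200 training scenes, `lr0 = 0.02`, and
the inverse-frequency class weights above. Head branch widths carry a floor
of 16 channels so tiny multipliers keep a usable classification tower; the
floor is inactive at nano scale, where the branch widths are 64 anyway. The
problem sizes were chosen so a full training-plus-evaluation cycle completes
in minutes on one CPU while still demonstrating learning: the desk run
halves its training loss well before epoch 30 and reaches mAP50 ≥ 0.8 on
held-out synthetic scenes (AP is computed at the family's usual validation
confidence of 0.001). The learning rate is higher than the field default
because the tiny model and easy scenes tolerate it; it was fixed from short
pilot runs on independent scene seeds.

## The synthetic scene generator

`gen_field_image()` emulates the structure of the UAV imagery, not its
appearance: noise-textured brown soil; seedlings as clusters of 3–5 green
elliptical lobes with size jitter (emulating stunted growth and uneven
branching); weeds as small tufts of 2–3 thin crossing blades in a slightly
different green — deliberately seedling-like; optional translucent pale
strips overlay the scene to mimic film glare and partial occlusion. Class
imbalance defaults to 4:1 seedlings:weeds, mirroring the scarcity of weed
samples in such fields. Object placement is rejection-sampled under a
maximum box-IoU constraint; labels are tight boxes around the drawn pixel
mask, so label fidelity is exact by construction. A scene is a pure function
of (spec, seed).

Weeds are drawn as multi-blade tufts rather than single blades because a
single 2-px blade at stride 8 almost never contains an anchor center, making
the class undetectable *by any* anchor-based detector of this family — a
degenerate condition rather than a hard one, and not representative of real
grass weeds, which present as clumps.

`gen_field_video()` places objects along a virtual strip and sweeps a camera
window across it at constant speed, returning per-frame ground-truth boxes
with persistent ids and the exact per-class number of frame-center-line
crossings; objects are placed so their centers pass the line mid-sweep. This
is the fixture that makes counting exactly verifiable.

What passing tests on these scenes does **not** show: robustness to real
soil/vegetation texture, lighting, blur, perspective, or to the long tail of
occlusion geometries. The generator validates wiring, losses, metrics and
counting logic — not field accuracy. Field-scale accuracy claims (AP on real
imagery) require the real dataset and GPU-scale training and are explicitly
out of scope.

## Evaluation and counting conventions

Matching is greedy per image and class: detections in decreasing score
order, each claiming the unmatched ground truth of highest IoU at threshold
0.5 (the usual choice matching an AP50 focus; ties break by ground-truth
index so runs are deterministic). AP integrates the monotone precision
envelope over recall ("all points"); a 101-point interpolation is available
behind a flag for comparability. Zero-denominator cases (no detections, no
ground truths) score 0 rather than NaN — sparse synthetic scenes make these
reachable. The confusion matrix attributes unmatched ground truths to a
background column and unmatched detections to a background row. FPS is pure
arithmetic on a supplied (preprocess, inference, postprocess) millisecond
breakdown; wall-clock instrumentation is hardware-dependent and deliberately
not part of any acceptance check.

Counting is direction-agnostic: a track is tallied the first time the sign
of (center − line) flips between consecutive observations, and its id is
never counted again, so oscillation cannot double-count. A track first seen
past the line has no crossing history and is not counted. The bundled
tracker is a greedy nearest-centroid associator with a class gate and a
drop-after-patience rule — deliberately simple fixture plumbing; any tracker
producing per-frame (id, class, box) records can replace it.

## Numerical choices and degenerate inputs

* IoU of two zero-area boxes is defined as 0 (avoids 0/0 on degenerate
  labels).
* Softmax is computed with the max subtracted; attention descriptors are
  plain spatial means.
* Batch normalization uses batch statistics in training and running
  statistics (momentum 0.03) in inference; a freshly assembled model's
  buffers default to mean 0, variance 1.
* Channel counts not divisible by 4 are a hard error in MSConv rather than
  padded: every stage width in the supported configurations is a multiple
  of 4, so padding could only hide a misconfiguration.
* The box-distribution decode clamps targets to `[0, reg_max - 1 - 1e-3]`;
  decoded boxes are clamped to the letterboxed canvas before NMS.
* Greedy NMS defaults: confidence 0.25, IoU 0.45 (the family convention).

## Known limitations

* The autodiff engine is single-threaded R plus compiled GEMM-style kernels;
  it is sized for desk-scale experiments, not field-scale training.
* The tracker has no motion model or re-identification; it is sufficient for
  the slow, smooth motion of the sweep fixture.
* The generator's film strips are vertical bands; real film glare is
  geometrically richer.
* mAP50-95 on synthetic scenes is pessimistic: procedural masks make tight
  high-IoU localization harder than the visual difficulty suggests.
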