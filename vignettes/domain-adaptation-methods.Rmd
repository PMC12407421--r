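---
title: "Methods: synthetic multiview imagery and domain-adaptive classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic multiview imagery and domain-adaptive classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Natural-history collections increasingly hold 3-D surface scans of
specimens. A classifier trained on *rendered* views of those scans is cheap
to supervise — every render inherits its specimen's species label — but must
ultimately work on *photographs*, whose backgrounds, lighting, optics and
noise differ systematically from renders. `morphadapt` is a self-contained,
desk-scale laboratory for studying that sim-to-real gap: it fabricates the
specimens, renders both image domains, trains classifiers under several
adaptation regimes, and measures what the models learned.

Everything is generated procedurally, so every experiment is exactly
reproducible from a configuration file and its seeds, and the ground truth
(species parameters, foreground masks, specimen identities) is known by
construction.

## The model

### Specimen forge

Each species is a point in a 10-parameter shape space built on a
superellipsoid cranium: overall length/width/height, two exponent
parameters controlling cross-section squareness, rostral taper, a sagittal
crest (amplitude and width), and a tooth-row bump train (amplitude and
frequency). A species is a base parameter vector; an individual specimen is
that vector plus seeded Gaussian within-species perturbation, clamped to
the valid ranges. Species bases are drawn by rejection sampling so that any
two species are separated by at least eight within-species standard
deviations in parameter space — species are distinguishable *by
morphology*, which is what the classifiers are supposed to learn. Meshes
are standardised to a common axial length and centred, mirroring the usual
practice of removing absolute size before classification.

### View sphere and renderer

Cameras sit on a yaw/pitch lattice: full yaw rings at a set of pitches plus
optional single poses at the two poles (where yaw is degenerate and is
collapsed to zero). The pose count is therefore
`(360 / yaw_step) * length(ring_pitches) + 2 * include_poles`; the
full-scale profile (20-degree yaws, pitches 0, ±30, ±60, both poles) gives
the canonical 92 poses.

The renderer is a deliberately small software rasterizer: perspective
projection, per-triangle barycentric coverage with a z-buffer, and flat
Lambertian shading (ambient plus diffuse) on a uniform background. It also
emits the exact foreground mask of each frame, which later anchors the
Grad-CAM focus score. No external rendering stack is used, so renders are
bit-identical across machines and runs.

### Photograph domain

Photographs are simulated by compositing the render over a procedurally
marked background (radial, turntable-like marks), then applying brightness
jitter, a colour cast, Gaussian blur, sensor noise and camera-distance
jitter. Two contracts matter:

* with **all magnitudes zero**, the output is *pixel-identical* to the
  clean render — the shift is fully ablatable, which acceptance tests
  exploit;
* the optional **session confound** keys the background pattern to the
  specimen's identity, creating a nuisance cue that correlates with the
  label inside a training set. A model can exploit it instead of
  morphology, which is exactly the failure mode the Grad-CAM analysis is
  designed to expose.

The rendered and photographed populations never share an individual: each
species' pool is partitioned into scanned and photographed specimens up
front.

### Data pipeline

Splits are *specimen-level*: all images of an individual land in one
partition. Per species, `floor(n * test_fraction)` specimens (at least 1,
at most `n - 1`) go to the test set. With 30 specimens at a 0.2 test
fraction this yields 24:6; with 29 (one corrupted scan dropped) it yields
24:5. `floor` rather than round-half-up is a deliberate design decision:
it is the only rounding rule consistent with both worked examples above.
A labelled-photograph *subset* keeps `floor(keep_fraction * n)` (at least
1) of each species' training specimens, so an 8:2 plan at 25% becomes the
2:2:6 train:test:unused layout. Training-time augmentation (translation,
horizontal flip, photometric jitter) is mild by default and never applied
to test images; the zero configuration is the identity.

### Classifier and training regimes

The classifier is a conv/ReLU/max-pool stack with a two-layer dense head
and softmax, implemented directly in R with im2col convolutions and
hand-written backpropagation (no deep-learning runtime is required). Two
backbones ship: `tiny` (two stages, 8 and 16 channels — the desk-scale
default) and `vgg19_like` (the 16-conv-layer VGG19 feature stack;
constructible at full scale, and able to load externally supplied weights,
though none are bundled). Two taps are exposed: the flattened
post-convolution features (for the MMD loss and t-SNE) and the final
convolutional activations (for Grad-CAM). Optimisation is Adam with
cross-entropy loss.

Six regimes cover the comparison:

| regime | labelled data | extra |
|---|---|---|
| `baseline` | synthetic | — |
| `photo_baseline` | all photographs | — |
| `photo_subset` | photograph subset | — |
| `mmd` | synthetic | + λ·MMD² to unlabelled photographs |
| `finetune` | photograph subset | starts from the MMD model's weights |
| `supplemented` | synthetic + photograph subset | — |

The MMD term is the biased (V-statistic) squared maximum mean discrepancy
between the feature matrices of a labelled synthetic batch and an
unlabelled photograph batch, under a Gaussian kernel summed over several
bandwidths (median-heuristic by default, scaled by 0.5/1/2). Its gradient
is computed analytically and injected into the feature tap during
backpropagation. The biased estimator is used as the loss because it is
non-negative and exactly zero on identical batches; the unbiased
U-statistic is also exposed for measurement.

Early stopping monitors the *training domain's* test loss with a patience
window (default 15 of 100 epochs), keeping the best epoch's weights. For
the `supplemented` and `finetune` regimes — where the interesting quantity
is performance on *both* domains — the monitored quantity is instead the
mean of the two domains' test accuracies. This is an explicit, reproducible
stand-in for the manual epoch selection such protocols usually involve.

### Evaluation suite

* **Accuracy and confusion matrices** on both test domains (rows are true
  classes and are normalised to sum to one).
* **Domain confusion**: both test sets' features are embedded jointly by an
  exact (O(N²)) t-SNE implementation, and mean silhouette widths over the
  ground-truth species labels are reported for the synthetic subset, the
  photograph subset and the pooled set. Well-adapted models show photograph
  clusters as compact as synthetic ones.
* **Grad-CAM focus scoring**: the heatmap is the rectified,
  gradient-weighted sum of final-conv activations, upsampled bilinearly and
  max-normalised. Let `f` be the fraction of heatmap mass above 50% of the
  maximum that falls inside the renderer's foreground mask; the image
  scores 3 if `f >= 0.9`, 2 if `f >= 0.6`, 1 if `f >= 0.3`, else 0. A model
  with 96 images at 3 and four at 2 averages 2.96. High scores mean the
  classifier uses the specimen, not the background.

## Parameters, defaults and why

* **Desk profile** (`default_experiment_config("desk_test")`): 4 species,
  6 scanned + 4 photographed specimens each, 12 poses (90-degree yaws at
  pitches 0/±40), 32 px frames, tiny backbone, 12 epochs. It runs
  end-to-end in minutes on one CPU and is the scale at which the package's
  own tests operate. These problem sizes are the package's choice, made for
  test-speed reasons, not a claim about any particular dataset.
* **Full profile** (`"full_scale"`): 16 species, 30 scanned (one
  dropped as corrupted) + 10 photographed specimens, the 92-pose lattice at
  720 px, 224 px training crops, the VGG19-like backbone, 100 epochs with
  patience 15. It reproduces the canonical dataset geometry — 479 assets,
  44,068 render tasks, a 35,328:8,740 synthetic split — and is intended for
  real hardware budgets; nothing in the test suite trains at this scale.
* **Photo-shift magnitudes** (brightness 0.15, colour cast 0.12, blur 0.8,
  noise 0.04, distance jitter 0.05) were fixed a priori to be visible but
  not class-destroying at 32 px, and are ablatable to zero.
* **t-SNE**: perplexity 30 (automatically reduced to `(N-1)/3` for small
  N), PCA to 50 dimensions first, 400 iterations with early exaggeration;
  exact pairwise affinities rather than approximations, since desk-scale N
  is small.

## What the forge does and does not emulate

The forge produces skull-*like* shapes with controllable between/within
species variation, which is sufficient to pose the sim-to-real problem: the
same morphology seen through two imaging pipelines. It does not attempt
anatomical realism (no teeth, sutures, or foramina), texture, or scanning
artefacts, and the photograph domain is a parametric caricature of real
studio photography. Consequently absolute accuracies and silhouette values
at desk scale are not comparable to any real-data study; only the
*qualitative structure* — cross-domain degradation, its reduction by MMD
alignment, supplementation and fine-tuning, and background-reliance under a
session confound — is expected to transfer, and that structure is what the
acceptance tests check.

## Numerical choices

* All randomness flows through saved-and-restored RNG state (`with_seed`)
  and a small LCG-based seed deriver, so every artefact is a pure function
  of the configuration seeds.
* MMD gradients are analytic and verified against finite differences to
  ~1e-10 in the tests, as are the convolution and dense-layer backward
  passes.
* Bilinear resizing uses half-pixel-centre mapping, making resize to the
  input size an exact identity (another contract the tests rely on).
* The biased MMD² of a batch with itself is exactly zero up to floating
  point, and kernel matrices are clamped against negative squared
  distances from catastrophic cancellation.

## Worked example

```{r, eval = FALSE}
library(morphadapt)

cfg <- default_experiment_config("desk_test")
res <- run_experiment(cfg, out_dir = tempfile("morphadapt_"))
res$comparison
```

The comparison table has one row per regime with per-domain accuracies,
epochs, the silhouette triple and the Grad-CAM mean. See the README for a
full transcript.
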