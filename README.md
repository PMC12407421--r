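# morphadapt

Synthetic multiview specimen imagery and domain-adaptive classification —
a self-contained, desk-scale laboratory for the *sim-to-real* gap in
collection-based image classification.

## The problem

Museum collections increasingly hold 3-D surface scans of specimens.
Renders of those scans make cheap, perfectly labelled training images for a
species classifier, but the classifier must ultimately work on
*photographs*, whose backgrounds, lighting, optics and noise differ
systematically from renders. Models trained purely on renders often
collapse on photographs — and, worse, models trained on few photographs can
quietly learn the *background* (a session confound) instead of the
specimen.

`morphadapt` reproduces this whole problem in software. It procedurally
forges skull-like specimens with controlled between/within-species shape
variation, renders them from a view-sphere camera lattice with its own
small rasterizer, simulates a photograph domain (marked backgrounds,
photometric shifts, noise), and trains a convolutional classifier — written
entirely in R, including backpropagation — under six regimes:

| regime | trains on |
|---|---|
| `baseline` | labelled renders |
| `photo_baseline` | all labelled photographs |
| `photo_subset` | a small labelled photograph subset |
| `mmd` | labelled renders + unlabelled photographs |
| `finetune` | photograph subset, starting from the MMD model |
| `supplemented` | labelled renders + the photograph subset |

## The core method

The `mmd` regime minimises, per batch,

```
L = CE(y, softmax(f(x_syn)))  +  λ · MMD²(φ(x_syn), φ(x_photo))
```

where `φ` is the flattened post-convolution feature map and `MMD²` is the
biased squared maximum mean discrepancy under a Gaussian kernel summed over
median-heuristic bandwidths `{0.5, 1, 2} · σ_med`:

```
MMD²(A, B) = mean K(A, A) + mean K(B, B) − 2 mean K(A, B)
```

The photograph batch needs **no labels**: the term only pulls the two
domains' feature distributions together. Its gradient is computed
analytically and injected at the feature tap during backpropagation.

Evaluation measures per-domain accuracy and confusion matrices, *domain
confusion* via an exact t-SNE embedding of both test sets with per-domain
silhouette scores over species labels, and *what the model looks at* via
Grad-CAM: each heatmap is scored 0–3 by the fraction of its hot mass (≥ 50%
of the maximum) inside the renderer's exact foreground mask (≥ 0.9 → 3,
≥ 0.6 → 2, ≥ 0.3 → 1). Low scores mean the classifier leans on the
background.

## Worked example

The shipped `desk_test` profile (4 species, 6 scanned + 4 photographed
specimens each, 12 poses at 32 px, tiny backbone) runs the forge → render →
split → train → evaluate pipeline in a few minutes on one CPU:

```r
library(morphadapt)

cfg <- default_experiment_config("desk_test")
res <- run_experiment(cfg, out_dir = "morphadapt_out")
print(res$comparison, digits = 3)
```

```
[08:47:57] stage forge+render+split finished in 27.7s
[08:48:29] stage train:baseline finished in 31.5s
[08:49:25] stage train:mmd finished in 56.0s
[08:50:00] stage train:supplemented finished in 35.6s
[08:50:02] stage evaluate:baseline finished in 1.7s
[08:50:03] stage evaluate:mmd finished in 1.5s
[08:50:05] stage evaluate:supplemented finished in 1.6s
        regime synthetic_accuracy photo_accuracy epochs silhouette_synthetic
1     baseline              0.958          0.667     12              -0.0829
2          mmd              0.958          0.708     12              -0.0735
3 supplemented              0.917          0.833     12              -0.0696
  silhouette_photo silhouette_combined gradcam_mean
1          -0.0925             -0.0498          1.5
2          -0.0681             -0.0381          1.3
3          -0.0790             -0.0370          1.1
```

The qualitative structure is the point: the render-trained `baseline` is
strong on its own domain and much weaker on photographs; adding the
unlabelled-photograph MMD term recovers part of the gap; `supplemented`
(renders + a small labelled photograph subset) recovers most of it.
At this tiny scale the absolute silhouette values are small (pose dominates
the 1024-dimensional features), but the pooled-domain silhouette still
improves monotonically with adaptation. Re-running with the same
configuration reproduces every number exactly.

Individual pieces are exposed directly:

```r
bank  <- generate_species_bank(n_species = 3, specimens_per_species = 4, seed = 1)
poses <- view_sphere_poses(view_sphere_spec())          # the 92-pose lattice
img   <- render(bank[[1]]$mesh, camera_pose(yaw = 40, pitch = 30),
                render_config(resolution = 128))
photo <- render_photo_domain(bank[[1]]$mesh, camera_pose(40, 30),
                             render_config(resolution = 128),
                             photo_domain_config(), rng_seed = 7)
mmd2(matrix(rnorm(40), 10), matrix(rnorm(40, 1), 10))   # two-sample statistic
```

A command-line front end wraps the same pipeline
(`inst/exec/morphadapt`): `morphadapt run-all --config cfg.yaml --out out/`,
with subcommands `forge`, `render`, `split`, `train`, `evaluate`.

## Documentation

The methods vignette (`vignettes/domain-adaptation-methods.Rmd`) describes
the shape space, the renderer, the photograph-domain model and its session
confound, the training regimes, the evaluation suite, default parameters
and the package's numerical choices and limitations.
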