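# afnnet

Nucleus segmentation for microscopy images with **AFN-Net**, a five-level
U-Net-derived encoder–decoder, implemented as a self-contained R package.
It is aimed at image-analysis researchers who want a fully inspectable,
dependency-light implementation of the architecture, its composite loss,
and the evaluation protocol — runnable end-to-end on a single CPU using
the package's synthetic nucleus generator, or on Data Science Bowl 2018
style mask directories.

Segmenting nuclei is hard where it matters most: the objects are small,
often touching, and their boundaries are blurred against textured
backgrounds. AFN-Net addresses this with three components on top of the
U-Net skeleton:

**Weighted Feature Enhancement Unit (WFEU)** — at every skip connection
the encoder feature and the upsampled decoder feature are concatenated
into `x` and fused by a gated interaction followed by an enhancement /
channel-alignment residual:

    x1  = σ(W1 * x + b1)            (dynamic weight map)
    x2  = GELU(W2 * x + b2)         (nonlinear branch)
    x3  = x1 ⊙ x2                   (interaction feature)
    out = GELU(W3 * x3 + b3) + (W4 * x + b4),   W4 a 1×1 convolution

**Double-Stage Channel Optimization Module (DSCOM)** — the two
high-resolution encoder levels each apply two repetitions of
`standard conv → depthwise conv → batch norm → ReLU`
(`C_in → C_out`, then `C_out → C_out`), preserving fine spatial detail
at low parameter cost. Levels 3–5 are pre-norm transformer stages over
the flattened feature map, entered through stride-2 patch-embedding
convolutions.

**Adaptive fusion loss** — training minimises

    L = α·BCE(P,G) + β·Dice(P,G) + γ·Boundary(P,G)

where the boundary term integrates the gradient magnitude of the
predicted probability field weighted by each pixel's exact Euclidean
distance to the ground-truth mask boundary:

    Boundary(P,G) = mean_x ‖∇σ(P)(x)‖₂ · D_G(x),
    D_G(x) = min_{y ∈ B_G} ‖x − y‖₂

with `B_G` the inner 4-connected boundary of `G`. Default weights are
`α = √2/2`, `β = γ = 1 + √2/2` (BCE moderately down-weighted, region
overlap and boundary accuracy up-weighted). See the methods vignette
(`vignettes/afnnet-methods.Rmd`) for every discretisation decision and
the reasoning behind it.

## Worked example

Generate a small synthetic dataset, train the tiny configuration for a
few epochs, and evaluate the held-out images:

```r
library(afnnet)

ds  <- synthetic_dataset(synthetic_spec(seed = 11), 200)
cfg <- train_config(lr = 3e-3, epochs = 20, batch_size = 8,
                    input_size = 64, restarts = 3, seed = 7)
fit <- train(cfg, ds, afn_config_tiny(seed = 7))
tail(fit$history[, c("epoch", "lr", "loss", "val_iou", "val_dice")], 3)
#>    epoch           lr     loss   val_iou  val_dice
#> 18    18 9.100322e-05 1.424410 0.9058462 0.9500354
#> 19    19 3.038985e-05 1.408692 0.9105427 0.9526094
#> 20    20 1.000000e-05 1.421653 0.9053415 0.9497280
```

Each history row holds the cosine-annealed learning rate, the mean
training loss (and its BCE/Dice/boundary components), and the
validation IoU and Dice at that epoch: after 20 epochs the tiny model
segments held-out synthetic nuclei at Dice ≈ 0.95 (`restarts = 3` races
three initialisations for one epoch before committing — narrow models
are init-sensitive). `fit$best_checkpoint`
points at the best-validation-Dice checkpoint, reloadable with
`load_checkpoint()`; `evaluate()` writes per-image metric tables
(CSV/JSON), and `predict_to_dir()` exports probability and mask PNGs.

A command-line interface wrapping the same functions is installed at
`inst/cli/afnnet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/afnnet.R", package="afnnet"))')" \
    synth --out data/synth --n 50 --size 64 --seed 0
```

with `train`, `eval`, `predict` and `ablate` subcommands driven by a
YAML config (`config_write()` / `config_read()`).

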