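# stainpipe

Histology slides are stained with hematoxylin and eosin (H&E), scanned, cut
into tiles, and classified — but a model trained on one scanner routinely
falls apart on another, because each scanner/laboratory combination renders
the same dyes with different colours. `stainpipe` is an R toolkit for
building and stress-testing tile-based whole-slide-image (WSI) classifiers
under exactly this *scanner domain shift*, with the duodenal-biopsy
(coeliac-disease) screening setting as its reference design. It provides:

- **Beer–Lambert stain algebra.** A pixel's optical density
  `OD = -log10(I / I0)` is a non-negative combination `OD = S c` of two
  3-vector dye absorption directions (the columns of the stain matrix `S`,
  hematoxylin and eosin) weighted by concentrations `c`.
- **Macenko stain-vector estimation**: the two stains are recovered as the
  percentile-bounded extreme angular directions of the foreground OD cloud
  inside its top-2 singular plane.
- **Stain normalization**: re-express a tile's concentrations against a
  fixed target matrix (`OD' = S_target c`), standardizing colour across
  scanners without touching the concentrations.
- **Stain jittering**: training-time augmentation that multiplies each of
  the six stain-matrix elements by an independent `U(0.75, 1.25)` draw
  before reconstruction.
- **Tissue-aware tiling**: Otsu segmentation, sliding-window extraction of
  224 px tiles at ×10 magnification (stride 112 at inference, 56 in
  training), the ≥10 % tissue-retention rule, and rotation/reflection
  augmentation via oversized 316 px tiles centre-cropped after rotation.
- **Slide-level aggregation**: a slide's score is its fraction of positive
  tiles; a slide is called positive when that fraction exceeds a threshold
  γ chosen to maximize accuracy; full metric suite (accuracy, sensitivity,
  specificity, precision, F1, ROC/AUC, bootstrap confidence intervals).
- **A synthetic slide generator** with planted stain matrices, tissue
  masks, class-dependent texture, and "virtual scanner" profiles, so the
  entire three-arm experiment — NP (no processing), SN (stain
  normalization), SJ (stain jittering) — runs end-to-end with no external
  data.

The full-scale deep backbone of the reference design is deliberately out of
scope; the classifier is a pluggable contract (augment → optional stain op
→ batch → binary cross-entropy/Adam loop) shipped with a desk-scale
summary-feature MLP backend.

## Worked example

```r
library(stainpipe)

# a virtual "base" scanner and a strongly shifted rescan of the same biopsy
base    <- scanner_profile(name = "base")
shifted <- shift_profile(base, 20, background_delta = c(-20, -12, -4))

slide <- generate_slide(slide_params(height = 448, width = 448,
                                     label = "positive", seed = 7), base)

# stain-vector recovery against the planted truth
S_hat <- estimate_stain_matrix(rgb_to_od(slide$image))
round(unclass(S_hat), 3)
#>   hematoxylin eosin
#> R       0.663 0.071
#> G       0.682 0.990
#> B       0.308 0.118

# tissue-aware tiling
mask  <- segment_tissue(slide$image)
tiles <- extract_tiles(slide$image, mask, tile_spec(), "inference", "s7")
length(tiles)          #> 9 tiles, all with >= 10% tissue

# normalize one tile to the packaged target matrix
norm <- normalize_stains(tiles[[1]]$pixels, default_target_stains())

# the three-arm cross-scanner replication at desk scale (one seed)
res <- run_shift_replication(seed = 11, arms = c("NP", "SN"), epochs = 12)
sapply(res, function(r) c(same = r$same$f1, shifted = r$shifted$f1))
#>            NP    SN
#> same    1.000 1.000
#> shifted 0.667 1.000
```

The last table is the package's core demonstration: trained with no stain
processing (NP), the classifier is perfect on its own scanner but collapses
on the shifted rescan of the *same* biopsies (F1 0.667 is the all-positive
call); with stain normalization of training and validation tiles (SN), the
shifted-scanner performance is rescued.

## Command line

```sh
Rscript -e 'stainpipe::stainpipe_cli()' simulate --n-pos 5 --n-neg 5 --size 512 --seed 1 --out data/
Rscript -e 'stainpipe::stainpipe_cli()' tile --image data/slide_001_pos.png --out tiles/
Rscript -e 'stainpipe::stainpipe_cli()' experiment --data data/ --out results/ --seed 1
```

Subcommands: `simulate`, `tile`, `normalize`, `jitter`, `train`,
`evaluate`, `experiment`, `qa-grid`. A `--config file.yaml|.json` may supply
any flag; explicit flags win.

## Vignette

`vignettes/stain-normalization-pipeline.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, and the numerical
design choices.
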