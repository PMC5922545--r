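# phenotray

Automated, high-throughput plant phenotyping from top-view tray images.

`phenotray` implements the image-analysis pipeline of a sensor-to-plant
phenotyping system: a camera visits stationary trays (by default 28 trays
of 32 pots in a 4 × 8 grid, photographed hourly from 09:00 to 21:00) and
the software turns the resulting stream of 1,920 × 1,080 frames into
per-plant growth curves. The package is aimed at plant biologists and
image-analysis engineers who need a tested, scriptable implementation of
each stage — and a synthetic-data generator that provides exact ground
truth for training and validation without a camera.

## Pipeline

1. **Rectification.** Four red fiducial markers on each tray are detected
   by an HSV colour threshold refined with an Otsu grayscale threshold;
   contours under 150 px are discarded and adjacent fragments merged.
   With pot size `Pw × Ph`, the marker centres map to the target
   coordinates `(2Pw, Ph)`, `(6Pw, Ph)`, `(2Pw, 3Ph)`, `(6Pw, 3Ph)` of the
   corrected image; the 3 × 3 homography `H` between source and target
   points is solved exactly (4-point DLT) and the frame is
   perspective-warped onto the `8Pw × 4Ph` canvas. Markers missing on a
   visit are recovered from the previous/next visit.
2. **Cropping & cataloging.** The canvas tiles into 32 pot images of
   224 × 224 px (`Pot01`…`Pot32`, row-major), stored as
   `F11_Pot01/F11_Pot01_<date>_<time>.png` so each pot's history sits in
   one folder. One cycle of 28 trays yields 896 crops; a default day
   yields 13 × 28 = 364 tray images and 11,648 crops.
3. **Features.** Each pot image is converted to CIE L\*a\*b\* and
   over-segmented into ~700 SLIC superpixels; the feature matrix is the
   N × 3 matrix of per-superpixel mean (L\*, a\*, b\*).
4. **Classification.** A binary plant/background classifier (random
   forest with 100 trees by default; RBF-kernel SVM and a 2 × 256
   sigmoid-MLP trained with Adam and dropout 0.7 are provided for
   comparison) labels each superpixel; labelled superpixels are
   re-broken into pixels to form the raw mask.
5. **Post-processing.** The mask is eroded (3 × 3, one pass) and only
   the connected component at the image centre is retained, removing
   moss blobs and leaves intruding from neighbouring pots.
6. **Growth analysis.** `batch_process()` walks a catalog tree and emits
   `tray,pot,date,time,area_px` records; `growth_series()` /
   `growth_slope()` extract per-pot trajectories and windowed
   least-squares slopes.

Classifiers are compared with image-grouped k-fold cross-validation
(k = 5), micro-averaged precision/recall/F1, precision–recall curves and
average precision (positive-rank estimator), repeated over reshuffled
folds; `compare_algorithms()` also scores a held-out test split drawn
from a shifted colour distribution to probe generalization across
acquisition environments.

## Worked example

```r
library(phenotray)

params <- sim_params(seed = 1)                    # 4 x 8 tray, 224 px pots
g <- generate_tray(params, day = 12)              # one distorted frame + truth
rect <- rectify_tray(g$image$image)               # detect -> homography -> warp
pots <- crop_pots(rect$image, tray_geometry())    # 32 pot images

pack  <- generate_groundtruth_pack(params, 100, seed = 1)
model <- train_classifier(assemble(pack), algorithm = "rf", seed = 1)

seg <- segment_pot(pots$Pot01, model)
seg$stages$areas
#>    raw eroded  final
#>   1626   1340   1167
```

The three numbers are the plant area in pixels after each post-processing
stage: the raw superpixel mask, the eroded mask (boundary ring removed),
and the centre-retained final mask (off-centre material such as moss or a
neighbour's leaf dropped). Cross-validated performance:

```r
cv <- cross_validate(assemble(pack), "rf", k = 5, seed = 1)
round(mean(cv$fold_f1), 4)
#> [1] 0.9934
```

the mean validation F1 of the plant class over the five image-grouped
folds.

A command-line wrapper is installed at `inst/scripts/phenotray`:

```sh
phenotray simulate --out raw/ --days 3 --seed 1
phenotray preprocess --in raw/ --out catalog/
phenotray train --out model.rds --n-images 100 --seed 1
phenotray analyze --root catalog/ --model model.rds --out results.csv
```

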