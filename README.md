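# canopyseg

Weakly supervised segmentation of small stress lesions — lettuce
tip-burn being the motivating case — on large, dense plant-canopy images,
using only image-level class labels as supervision.

In a plant factory, a table of ~1,000 densely packed plants is imaged
from above; tip-burn lesions are on the order of 5×5 pixels at that
scale, rare, sparse, and hidden in canopy texture. Pixel-level
annotation is impractical, but labeling 64×64 crops as *lesion* /
*healthy* is cheap. `canopyseg` turns that weak signal into a
full-resolution mask with every detection attributed to its tray and
cell, for growers and phenotyping pipelines that need to find and count
stressed plants automatically.

## The method

For a tile $X \in \mathbb{R}^{M\times N\times 3}$:

1. **Hard-stride splitting.** All $p\times p$ patches at stride $s \ll p$
   (default $p=64$, $s=8$), $k_1 = \lfloor (M-p)/s\rfloor + 1$ per axis,
   no padding; every interior pixel is covered by $(p/s)^2 = 64$ patches.
2. **Patch classification.** Each patch, rescaled to the classifier
   input, gets a positive-class probability from a classifier trained on
   image-level labels only (any backbone satisfying the predict
   contract; a small built-in CNN serves desk-scale work).
3. **Attention map.** Patch probabilities are projected back over their
   footprints, summed, and divided by the per-pixel overlap count
   $A_{overlap}$: an $M\times N$ map whose overlap averaging resolves
   structure at the stride scale.
4. **Graph refinement.** Tile and map are re-cut into 8×8 nodes (3168
   for a 352×576 tile). Nodes are connected when the Jensen–Shannon
   divergence of their RGB+HSV colour histograms is below $\beta$, and a
   per-tile graph convolutional network,
   $Z = \mathrm{softmax}(\hat A\,\mathrm{ReLU}(\hat A\,\mathrm{ReLU}(\hat A X W^{(0)})W^{(1)})W^{(2)})$
   with $\hat A = \tilde D^{-1/2}(Adj + I)\tilde D^{-1/2}$, is trained
   transductively on pseudo-labels seeded from the attention peaks,
   validated by re-classifying each candidate node's own block, and
   cleaned against the similarity graph. The refined node probabilities
   replace the smeared attention cone.
5. **Reconstruction.** Node predictions are thresholded, mapped back to
   source coordinates, merged across tiles, and every connected
   component is attributed to a (tray, cell) of the growing hierarchy.

Accuracy is reported patch-wise:
$\mathrm{DSC}_{patch} = 2|X\cap Y|/(|X|+|Y|)$ and IoU over selected vs
predicted node sets. A deterministic synthetic generator (dense leaf
texture, sparse 4–12 px lesions with exact masks, plus single-leaf
images) stands in for proprietary canopy data; the methods vignette
(`vignettes/canopy-segmentation-methods.Rmd`) documents every model
component, default, and limitation.

## A worked example

```r
library(canopyseg)
set.seed(1)

can <- generate_canopy(canopy_spec(seed = 11))   # 352 x 576 tile + mask
print(can)

tr  <- generate_patch_training_set(150, seed = 101)
va  <- generate_patch_training_set(60,  seed = 202)
clf <- train_patch_classifier(tr$patches, tr$labels,
                              va$patches, va$labels,
                              epochs = 40, seed = 11)
print(clf)

seg <- run_pipeline(can$image, clf, seg_config())
summary(seg)

gt   <- gt_node_set(can$mask)
pred <- seg$tiles[[1]]$positive_nodes
cat(sprintf("patch-level Dice vs ground truth: %.3f\n", dsc_patch(gt, pred)))
```

which prints:

```
synthetic_canopy: 352 x 576, 4 lesion(s), 0.15% lesion pixels
patch_classifier: input 32 x 32 x 3, classes: healthy, lesion
  trained 40 epochs, final loss 0.0468, val accuracy 1.000
canopy_segmentation: 352 x 576, 4 region(s), 0.473% positive pixels
regions (tray, cell, bbox, area, mean prob):
 region tray_row tray_col cell_row cell_col  r0  r1  c0  c1 area_px mean_prob
      1        1        1        1        1 185 200 177 192     256 0.9994668
      2        1        1        1        1 233 248 337 352     192 0.9999992
      3        1        1        1        1 105 120 449 464     256 0.9989971
      4        1        1        1        1 201 216 481 496     256 0.9999996
patch-level Dice vs ground truth: 1.000
```

All four painted lesions are recovered as separate regions with their
bounding boxes and mean refined probability; the patch-level Dice
compares the predicted node set against the nodes genuinely containing
lesion pixels. `run_ablation()` reproduces the refinement comparison
(attention-threshold baseline vs 2-/3-layer GCN vs node-doubling), and
`write_segmentation()` exports the mask (PNG), the probability map
(16-bit TIFF) and the region report (JSON). A thin command-line wrapper
lives in `inst/cli/canopyseg.R` (`run`, `train-classifier`,
`make-fixtures`, `ablate`).

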