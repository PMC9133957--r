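---
title: "Weakly supervised lesion segmentation on dense canopies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised lesion segmentation on dense canopies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(canopyseg)
```

## The problem

Plant factories grow lettuce densely packed on tables — trays of cells,
one plant per cell, about a thousand plants under one camera. Tip-burn, a
calcium-related physiological stress, shows up as small necrotic
discolourations at leaf tips: at table-camera resolution a lesion is on
the order of 5×5 pixels, rare, sparse, and easily hidden in the canopy
texture. Finding these lesions and attributing them to a tray and cell is
a segmentation problem, but pixel-level annotation of dense canopies is
impractical. The only supervision `canopyseg` assumes is image-level:
crops labeled "lesion" or "healthy".

The package turns that weak signal into a pixel-attributable mask in five
stages: hard-stride patch splitting, patch classification, attention-map
reconstruction, graph-convolutional refinement of node pseudo-labels, and
inverse reconstruction with tray/cell attribution.

## Splitting with hard strides

A tile $X \in \mathbb{R}^{M\times N\times 3}$ is cut into all patches of
size $p_x \times p_y$ whose footprint lies fully inside the image
(no padding), at strides $(s_x, s_y)$:

$$k_1 = \lfloor (M - p_x)/s_x \rfloor + 1, \qquad
  k_2 = \lfloor (N - p_y)/s_y \rfloor + 1.$$

The floor convention is forced by the no-padding requirement (and by the
canonical worked example: 195 columns with 64 px patches at stride 8 give
$k_2 = 17$, not 18). With the default hard stride — stride 8 against
patch size 64 — every interior pixel is covered by $8 \times 8 = 64$
patches. Patch $(r, c)$, 1-based, covers the half-open block starting at
pixel $((r-1)s_x + 1,\; (c-1)s_y + 1)$; `patch_to_pixel()` is the exact
inverse bookkeeping used for reconstruction, and `accumulate_overlap()`
counts, per pixel, how many patches cover it (the product of two per-axis
coverage counts).

## From patch probabilities to an attention map

Each patch is rescaled to the classifier input size (area-averaged
resampling, which is exact block averaging for integer factors) and
scored; the positive-class probabilities form a $k_1 \times k_2$
configuration. Projecting every patch's probability back over its
footprint, summing, and dividing by the overlap counts yields the
overlap-averaged attention map — the same spatial size as the tile, with
values in $[0,1]$. The averaging is what creates resolution: a single
64 px patch knows only that a lesion is *somewhere* inside it, but the 64
overlapping patches through a pixel vote, and their average varies at the
stride resolution (8×8 blocks for the default geometry; at stride 1 it
would be per-pixel). Pixels covered by no patch (possible only when the
strides do not tile exactly; the canonical 352×576 geometry tiles
exactly) are flagged by overlap count 0 and excluded.

Two properties of the map matter downstream and are worth stating
honestly:

* **The cone is smear.** Around an isolated detection the averaged map
  decays roughly linearly over a patch width in each direction. A plain
  threshold at 0.5 therefore selects a region about the size of a patch,
  not the size of the lesion — the thresholded map is a coarse baseline,
  not a segmentation.
* **Borders are blunter.** Within one patch width of the tile border a
  pixel has systematically fewer covering windows, so the same averaging
  has less spatial selectivity there. The synthetic generator keeps
  lesions at least one patch width (72 px) inside the tile for this
  reason; behaviour at tile borders is a documented limitation of the
  windowed-average construction.

## Nodes, colour histograms, and the similarity graph

The tile and its attention map are re-cut into non-overlapping 8×8 blocks
("nodes"): 44 × 72 = 3168 nodes for a 352×576 tile. Each node carries its
raw pixels, flattened to a vector of length $k = 192$, and one
probability — the mean of its attention block (exact, because the map is
block-constant at this geometry). Nodes are indexed column-major,
$idx(r,c) = w(c-1) + r$ with $w$ the grid row count.

Each node also gets a non-parametric colour signature: its 64 RGB pixel
values in all three channels plus their HSV transform (hue scaled to the
common $[0,1]$ range), $64 \cdot 3 \cdot 2 = 384$ values, binned into a
64-bin equal-width histogram and normalized. Two nodes are connected in
the per-tile graph when the Jensen–Shannon divergence of their
histograms,

$$\mathrm{JSD}(q_i \| q_j) = \tfrac12 KL(q_i \| m) + \tfrac12 KL(q_j \| m),
  \quad m = \tfrac12 (q_i + q_j),$$

falls below a threshold $\beta$. JSD is symmetric (which the adjacency
matrix must be) and bounded by $\log 2$; zero-count bins are handled by
adding $10^{-12}$ to both histograms and renormalizing, natural log
throughout. With self-loops added, $A = Adj + I_n$, and degree
normalization $\hat A = \tilde D^{-1/2} A \tilde D^{-1/2}$, $\hat A$ is
the first-order spectral propagation operator.

$\beta$ is a dataset property, not a universal constant: it must sit
between the divergence of same-surface node pairs and the divergence
separating lesion-tinged nodes from background. For the dark,
homogeneous canopies of the reference tip-burn setting the operating
value is 0.005 (the `build_adjacency()` default). The synthetic canopies
generated here have somewhat higher within-surface dispersion (their
adjacent-pair divergence has median ≈ 0.03, while lesion-bearing nodes
sit ≥ 0.1 from background), so the pipeline default is
`beta = 0.03`; `calibrate_beta()` places the threshold at a chosen
quantile of the sampled pairwise-divergence distribution for new
datasets.

## Graph-convolutional refinement

The refinement network is the standard first-order graph convolution:

$$H^{(t+1)} = \sigma(\hat A H^{(t)} W^{(t)}), \qquad H^{(0)} = X_\varphi,$$

with ReLU activations, a row-wise softmax after the last
(activation-free) layer, hidden widths 64 and 32 for the 3-layer default
(a 2-layer variant uses width 64), and cross-entropy on the labeled nodes
minimized with Adam at learning rate 0.01 for up to 200 epochs. Layers
carry bias vectors, as in the reference implementation of this
convolution; `gcn_forward(..., bias = NULL)` reproduces the strictly
bias-free propagation form. Because each tile is its own transductive
problem, one graph is built and one network trained per tile; batching
across tiles would simply make the propagation block-diagonal.

### Where the pseudo-labels come from

This is the step where design choices genuinely matter, because the raw
material is poor: thresholding the attention map at 0.5 labels the whole
smear cone positive — around 25 background nodes for every node that
actually carries lesion colour — and lesion nodes are well under 1 % of
the grid. Two failure modes follow immediately and we verified both over
many generator seeds: an unweighted loss on all nodes collapses to the
majority class (the lesion cluster contributes ~0.2 % of the gradient),
and naively up-weighting positives makes the network drag whole
background regions positive trying to fit smear nodes that are
colour-indistinguishable from background. The labeled set is therefore
built in four moves, each with a one-line justification:

1. **Local-peak relative seeding.** Every local maximum of the node-score
   surface above 0.5 is a detection; nodes scoring at least 0.75 of
   their local peak are candidate positives. Relative-to-peak, because
   absolute confidence varies with the backbone; per-peak, because a
   globally strongest lesion must not absorb the seed budget of weaker
   ones.
2. **Decomposition-principle validation.** The same classifier that
   scored the 64 px patches classifies each candidate's own rescaled 8 px
   block. A crop of canopy shares the feature statistics of the whole —
   the assumption the entire pipeline rests on — so a candidate that is
   genuinely lesion-coloured classifies as lesion at node scale too,
   while a pure-background node that merely sits inside a lesion's
   attention cone classifies as healthy and is dropped.
3. **Neighbourhood-consistency demotion.** A surviving positive whose
   graph neighbours are mostly non-positive is demoted to unlabeled
   (iterated to a fixed point): its colour is indistinguishable from
   confirmed background, so its label could only be fit by dragging that
   background along.
4. **A negative band and an unlabeled band.** Nodes below 0.1 of the
   global peak are labeled negative; everything between the bands — the
   ambiguous skirt of the cone — stays unlabeled, in the semi-supervised
   spirit of transductive node classification.

The loss is class-balanced with the positive class carrying 0.3 of the
labeled weight: enough that a handful of seed nodes is heard against
thousands of negatives, low enough that fitting a single inseparable
mislabeled node is never worth the collateral misclassification of its
background twins. After training, the node probabilities are replaced by
the positive-class column of the network output (kept soft; the mask
threshold is applied only at export), and the final mask is the union of
the positive node blocks, reconstructed to source coordinates.

If the seeds degenerate to a single class, or no node score reaches the
detection floor of 0.5, refinement is skipped and the grid passes
through unchanged — with no confident detection there is nothing to
sharpen, and seeding off a noise peak would hallucinate lesions on
healthy tiles.

### The ablation variants

`run_ablation()` compares, per image and averaged: thresholding the
attention map (`ram`), 2- and 3-layer refinement (`gcn2`, `gcn3`), and a
node-doubling variant (`gcn3_double`) in which the positive seed set is
doubled by admitting the equally many next-most-probable non-seed nodes.
The doubling interpretation is deliberate: the admitted nodes have, by
construction, lower probability of truly being lesion, so the variant
tests sensitivity to seed purity — and degrades accordingly, which is
the direction the refinement design predicts.

## The patch classifier

The classifier contract is minimal: an input size, a class vocabulary,
and a batch predict returning per-image probability vectors. Production
use plugs in any fine-tuned backbone satisfying the contract. The
in-package trainable model is a small convolutional network —
conv 5×5 (8 filters), ReLU, 2×2 max pool, conv 3×3 (16 filters), ReLU,
global max pooling, dense softmax — trained with Adam, early stopping
and a reduce-on-plateau schedule. The global max pool matters: the task
is "a small lesion *somewhere* in the patch", and a dense network on
flattened pixels has no position invariance (we measured it stuck near
chance on this task), whereas a max-pooled convolution detects the
lesion wherever it sits. The default input size is 32 px; training from
scratch uses learning rate 0.01 (a plateau schedule starting at 0.1
suits fine-tuning a pretrained backbone, not from-scratch Adam, though
both remain configurable).

Augmentation for 64 px training patches follows the standard policy for
this material: rotation in [0, 90]° with reflection fill, up–down and
left–right flips, median-cut quantization to 8 colours, zoom-in by
scale-and-crop (scale in [1, 1.5]), zoom-out by edge padding (0–8 px per
side), Gaussian blur with σ in (0.5, 2). Ranges the source material
leaves open (zoom magnitudes, interpolation, fill rule) are stated
defaults, all configurable.

## Single-leaf datasets

For class-folder leaf datasets (one leaf on a near-uniform background),
preprocessing bootstraps its own supervision: the four 8×8 corner
patches of each image are background by construction, six 8×8 patches
from the image centre are foreground, and a small MLP (192 inputs,
hidden 64/32) learns the separation, pooled across the dataset. Every
pixel is then scored by its centred 8×8 window, the largest connected
foreground component is kept (speckles would distort the crop),
background is zeroed to exactly (0,0,0) so it cannot influence
downstream classification, and the image is cropped to the foreground
bounding box and resized (264×400 for long-format leaf collections,
256×256 otherwise). Pooled rather than per-image training is the
default because corner/centre labels are few per image and the
background is homogeneous within a dataset; per-image training is a
matter of passing a single image.

## The synthetic data generator

No public canopy dataset with ground-truth lesion masks exists, so the
generator is first-class, tested code that emulates the statistical
structure the method assumes, with exact masks:

* a dense texture of overlapping elliptical "leaves" (semi-axes
  24–56 px — individual leaves span tens of pixels at a
  few-plants-per-tile imaging scale), hue 0.27–0.33, saturation
  0.55–0.75, value 0.40–0.60: one cultivar under uniform LED light has a
  deliberately narrow colour distribution;
* a smooth multiplicative brightness field (±3 %) and 0.5 % additive
  pixel noise, consistent with well-lit 8-bit photography;
* a Poisson(3) number of lesions per tile, diameters 4–12 px,
  yellow-brown (hue 0.07–0.13), placed non-overlapping and at least
  72 px from tile borders; the mask marks exactly the painted pixels;
* single-leaf images: one shaded green ellipse on a brown background,
  corners guaranteed leaf-free, with optional lesion spots inside the
  leaf.

Images are snapped to the 8-bit lattice so PNG round-trips preserve
levels exactly. What the generator does *not* emulate — and what passing
tests therefore do not establish for real data — includes specular
highlights and shadows, leaf venation and serrated boundaries, occlusion
layering, chlorosis gradients around necrotic tissue, camera vignetting,
and lesions at tile borders. The colour separation between lesion and
canopy is clean by construction; real tip-burn at early stages is
subtler.

## Evaluation

Ground-truth masks make patch-level evaluation exact here: the selected
node set contains every node with at least `gt_min_pixels = 4` lesion
pixels (a one-to-three-pixel sliver is not a patch an annotator would
select), the predicted set is every node with refined probability at
least 0.5, and

$$\mathrm{DSC}_{patch} = \frac{2|X \cap Y|}{|X| + |Y|}, \qquad
  \mathrm{IoU} = \frac{|X \cap Y|}{|X \cup Y|},$$

with both defined as 1 when both sets are empty (a correctly empty
prediction on a healthy tile). Because nodes are uniform blocks these
equal the pixel metrics on the corresponding block masks, and
$\mathrm{DSC} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$ always.

## Numerical choices and degenerate inputs

* Coordinates are 1-based and column-major throughout, as in base R;
  node flattening uses R's native column-major order and is exactly
  invertible.
* Area-averaged resizing uses exact interval-overlap weights; integer
  downscaling factors reduce to block means.
* Histogram smoothing adds $10^{-12}$ before the divergence; the
  pairwise scan (compiled) exploits per-bin non-negativity of the JSD
  contribution to terminate early once a pair exceeds $\beta$.
* Overlap-averaged collapse guards count-0 pixels (they stay 0); on
  integer-valued images the split–collapse round trip is exact.
* Glorot-uniform initialization and fixed seeds make classifier and GCN
  training reproducible; Adam gradients in the dense engines are clipped
  at global norm 5.
* Degenerate cases pass through with a warning where the contract allows
  nothing better: single-class training data errors out, single-class
  pseudo-label seeds skip refinement, an empty foreground skips the
  leaf crop.

## Problem sizes used by the tests and the acceptance script

The shipped tests train the small CNN on 150 patches per class (held-out
accuracy is asserted ≥ 0.95) and run the full pipeline plus the ablation
on three 352×576 synthetic canopies; the acceptance script uses 250
patches per class and four canopies. These sizes were chosen as the
smallest at which the classifier saturates and the per-image patch-Dice
stabilizes; nothing in the method depends on them.

## Known limitations

* The attention map's spatial selectivity degrades within a patch width
  of tile borders (fewer covering windows); lesions there are localized
  more coarsely.
* Refinement can only keep lesion nodes it can distinguish by colour:
  nodes whose blocks contain only a few lesion pixels are sometimes
  dropped, which bounds patch-Dice below 1 even with a perfect
  classifier.
* $\beta$, the seed thresholds and the class-balance share are dataset
  operating points, not universal constants; `calibrate_beta()` and the
  configuration surface exist precisely because a new dataset will need
  its own.
* The transductive design re-trains a small network per tile; that is
  the method's cost model (seconds per tile on one CPU core), not an
  implementation accident.
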