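---
title: "Coarse-to-fine kidney tumor segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine kidney tumor segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephroseg)
```

## The problem and the pipeline

Kidney tumors occupy a tiny fraction of an abdominal CT slice, and a single
network asked to segment background, kidney and tumor at full resolution
spends most of its capacity on background. nephroseg implements the standard
remedy, a two-stage cascade:

1. **Coarse stage.** A binary network sees the full slice and labels
   kidney-plus-tumor as one foreground class, providing localization only.
2. **ROI extraction.** Each 8-connected foreground component is covered by a
   fixed-size square window: components that fit within 128 pixels per side
   get a 128-pixel window, anything larger gets 256. Windows are centred on
   the component and translated — never shrunk — to stay inside the canvas.
3. **Fine stage.** Each window is cropped, contrast-enhanced with the
   fuzzy-set transform, rescaled to the fine input grid, and segmented into
   background / kidney / tumor by a second network. Predictions are pasted
   back onto a zero canvas, so everything outside the windows stays
   background.

Both networks share one architecture: a U-shaped encoder–decoder whose
convolution blocks are *recurrent-residual parallel-convolution* (R2P)
blocks and whose skip connections pass through *attention gates*, with
Leaky-ReLU activations throughout.

## Fuzzy-set gray-level enhancement

Each pixel's normalized gray value $m \in [0,1]$ is fuzzified into three rule
memberships — dark, gray, bright — with breakpoints $b_1 = 0.15$,
$b_2 = 0.43$, $b_3 = 0.71$: dark is 1 below $b_1$ and falls linearly to 0 at
$b_2$; bright rises linearly from 0 at $b_2$ to 1 at $b_3$; gray is the
triangular complement. The rules *darken dark pixels, keep gray pixels, and
brighten bright pixels*: collapsing the memberships by the center-of-gravity
method with output singletons $v_d, v_g, v_b$ gives

$$v_0 = \frac{\mu_d v_d + \mu_g v_g + \mu_b v_b}{\mu_d + \mu_g + \mu_b}.$$

The singleton values are not uniquely determined by the rule statement; the
defaults $v_d = 0$, $v_g = 127$, $v_b = 255$ are inferred from the
coefficients of the closed-form transform below.

The closed-form piecewise transform is implemented **literally as
published**, including the 0.45 offset in its third branch:

$$f(m)=\begin{cases}0 & 0 \le m < 0.15\\
(m-0.15)/0.28\times 127 & 0.15 \le m < 0.43\\
(m-0.45)/0.28\times 255+(0.71-m)/0.28\times 127 & 0.43 \le m < 0.71\\
255 & \text{otherwise.}\end{cases}$$

That offset makes the transform discontinuous at $m = 0.43$ (the second
branch reaches 127 while the third starts near 108.8) and at $m = 0.71$
(the third branch tops out near 236.8 before jumping to 255). We deliberately
preserve the discontinuities — fidelity first — and expose a documented
`continuous = TRUE` mode that substitutes 0.43 for 0.45, which closes both
gaps. The transform is monotone *within* each branch but not globally; tests
assert exactly that.

```{r fuzzy}
enhance_pixel(c(0.10, 0.29, 0.50, 0.90))
```

`enhance_image()` min–max normalizes the image, then evaluates the transform
through a lookup table over the input bit depth (8 or 16); the LUT result is
bit-identical to a per-pixel loop because both use the same normalization
arithmetic. Integer output rounds half to even before clamping to
$[0, 255]$. A constant image has no defined normalization and passes through
with a warning.

**How the cascade maps intensities onto $m$.** The published method never
states the mapping from raw intensities to $[0,1]$. Per-image min–max (the
`enhance_image()` convention) makes the transform's *effective* breakpoints
depend on image content: on an ROI crop whose maximum is modest — for
example when percentile clipping has flattened a bright lesion to the upper
clip bound — normal kidney tissue lands near or above the $b_3 = 0.71$
saturation breakpoint, and kidney and bright tumor both map to 255,
destroying exactly the contrast the fine stage needs. The cascade therefore
feeds the fine network `enhance_windowed()`: a *fixed* window on the
foreground-z-scored scale, $z \in [-3, 3] \mapsto m \in [0, 1]$ (the
window/level convention of CT display). Because preprocessing standardizes
the foreground to mean 0 and SD 1, kidney tissue sits at $m \approx 0.5$ —
the gray plateau, "keep gray pixels gray" — while dark and bright lesions
saturate toward 0 and 255, which is the rule semantics stated by the method.
The window is fixed by the z-scoring semantics (foreground ±3 SD), not
fitted per patch, so the same tissue class always lands on the same branch
of the transform in training and inference alike.

## Data preparation

Volumes are cut into axial slices and **slices without any kidney marker are
discarded**. Intensity outliers (e.g. metal artifacts) are handled by
clipping the pooled training intensities to their 0.5th–99.5th percentiles
(linear interpolation between order statistics, pinned for
reproducibility); clipped intensities are then z-scored by the mean and
standard deviation of the *foreground* (label > 0) pixels. Statistics are
fit once on the training pool and frozen for test-time application — one
shared rule, no leakage. Whether the percentiles should be global or
per-volume is not determined by the method description; we chose global over
the pool, which makes the clip bounds a property of the dataset rather than
of individual volumes.

## The R2P block and attention gate

A *recurrent conv layer* computes an initial convolution $x_1$ of its input
and then $t$ accumulation steps $h \leftarrow \phi(\mathrm{BN}(W_r * h +
x_1))$ with shared recurrent weights; $t = 0$ reduces it to a plain
conv–norm–activation layer. An R2P block stacks two recurrent conv layers
per *parallel branch* (one branch per kernel size, e.g. 3×3 and 5×5),
concatenates the branch outputs channel-wise, projects back to the block
width with a 1×1 convolution when there is more than one branch, and adds a
residual copy of the input (1×1-projected when channel counts differ).

The attention gate weights encoder skip features $x$ by a mask computed from
the coarser decoder signal $g$: $g$ is upsampled to $x$'s grid, both are
1×1-projected to half of $x$'s channels, summed, passed through Leaky-ReLU,
projected to one channel and squashed by the logistic function. The output
is $x$ multiplied pixel-wise by the mask. With the final projection zeroed
the mask is exactly 0.5 everywhere — a property the tests exploit as an
exact oracle.

Defaults the method statement leaves open (recorded here as design
decisions):

* recurrence steps `t = 2`, the convention of the recurrent-residual family;
* `base_filters = 32`, doubled per level;
* batch normalization after every convolution (conv → norm → activation) and
  dropout 0.2 at the bottleneck — our reading of "a 20% batch normalization
  layer", which most naturally parses as a 0.2 dropout rate next to batch
  normalization;
* 2×2 max pooling down, nearest-neighbour ×2 followed by a 3×3 convolution
  up;
* Leaky-ReLU slope 0.01.

Tensors are `(rows, cols, channels, batch)` arrays — column-major R order
keeps convolution access contiguous. Forward and backward passes are
implemented in the package (im2col lowering to BLAS matrix products, exact
hand-derived gradients, verified against finite differences), with Adam as
the optimizer.

## ROI bookkeeping

`expand_roi()` implements the two-case window rule. The window ladder
`c(128, 256)` is a parameter: on canvases smaller than the nominal window
the side is capped at the canvas, and the desk profile (below) uses a
proportionally scaled ladder. 256-pixel windows are downscaled by a factor
of 2 to the fine input grid (bilinear for images, nearest for labels) and
fine predictions are upscaled back by nearest neighbour; 128-pixel windows
pass through untouched. Overlapping windows are pasted in
component-size-descending order so smaller, later windows win locally — the
order must be pinned for determinism even though typical anatomy never
produces overlaps.

## Tumor-size balancing

Tumor cross-section areas are counted per 8-connected component of the
tumor label over the fine-stage training crops and binned into a fixed-width
histogram (500-pixel bins at full scale). Bins below the largest bin's count
are topped up with augmented copies of their own samples until all non-empty
bins are equal. The augmentation menu is horizontal flip, vertical flip,
right-angle rotations, integer shifts (image padded with its intensity
floor, label with background), and mirror — read as the flip about the main
diagonal so it is distinct from the axis flips. Rotations are restricted to
right angles by default to avoid label interpolation. A shift that would
push tumor pixels off the patch changes the sample's bin, so it is rejected
and resampled. Samples are assigned to bins by their total tumor pixel
count; the originals are always retained exactly once.

## Evaluation

Per image and class, overlap is scored by the smoothed Dice coefficient

$$\mathrm{Dice} = \frac{2|A\cap B| + 1}{|A| + |B| + 1},$$

whose +1 terms make the empty-vs-empty case score 1 instead of 0/0. Kidney
Dice compares `label == 1` masks by default (strict mode: tumor pixels are
not kidney); a union mode (`label >= 1`) is provided because the published
per-class definition is ambiguous. The composite score is the arithmetic
mean of the two class means, reported at 3 decimals. Reported scores round
half away from zero on the decimal value: plain IEEE `round()` follows the
binary representation and would turn a true decimal 0.9295 into 0.929,
which contradicts the published worked examples.

## Synthetic phantoms

The generator emulates the *structure* the cascade assumes, not CT physics:
one or two bright elliptic-cylinder kidneys extruded over a sub-interval of
slices on a dark background, each optionally containing a darker or brighter
circular-cylinder tumor strictly inside the kidney (containment is enforced
with a 1.5-pixel margin), plus Gaussian noise and sparse extreme-intensity
artifact voxels for the clipping step to remove. Extruding 2D shapes keeps
the tumor's per-slice component area constant, so `tumor_area_range` is
honoured on every slice — a sphere could not guarantee that at its caps.
Tumor centres snap to the pixel lattice so the rasterized disk area is an
exact, precomputable function of the radius.

What passing tests on phantoms do **not** show: robustness to soft-tissue
contrast, partial-volume boundaries, anatomy-dependent kidney shape, or
scanner artifacts with spatial structure. Phantom results validate the
pipeline's mechanics and trainability, not clinical performance.

Default phantom conditions: 96-pixel slices, 1–2 kidneys, tumor probability
0.7, tumor areas 60–280 px, noise SD 8 on a background/kidney/tumor
intensity palette of roughly 30/160/(95 or 225), artifact rate 5·10⁻⁴.
Intensities are separated by several noise SDs — a deliberately learnable
task sized for CPU training.

## Desk profile and problem sizes

`desk_profile()` bundles the configuration used by the package's end-to-end
test: 96-pixel slices; depth-3, 8-filter networks with single-kernel (3×3)
blocks and one recurrence step; ROI ladder `c(48, 96)` (the 128/256 rule
scaled to the 96-pixel canvas, so the cascade still performs genuine
cropping); fine input 48; Adam with learning rate 0.001 and batch size 8,
five epochs per stage. The published full-scale settings (512-pixel slices,
128/256 windows, 500 steps × 100 epochs on GPU) remain the defaults of the
corresponding configuration objects; the desk profile is a named, scaled
instance, chosen so a complete train-and-evaluate cycle is a single-CPU job.
The coarse schedule is shorter than the fine one because binary
localization of bright ellipses converges in a few dozen steps, while
3-class boundary accuracy inside ROIs is the harder optimization.

## Numerical choices

* Percentiles: `quantile(type = 7)` (linear interpolation), pinned.
* Connectivity: 8-connected everywhere (a diagonal-touching kidney mask must
  not split into two ROIs).
* Integer rounding of enhanced gray levels: round half to even, then clamp.
* Composite-score rounding: half away from zero on the decimal value, at 3
  decimals.
* Max-pool gradient ties break toward the first maximal entry in a fixed
  scan order.
* He-normal weight initialization; all randomness flows through explicit
  seeds, and every generator/trainer restores the caller's RNG state.
* Degenerate inputs: constant images pass through enhancement with a
  warning; constant foreground makes preprocessing statistics an error; an
  all-background coarse mask short-circuits the cascade to an all-zero
  prediction.

## Known limitations

* The fine stage is trained on ground-truth-derived ROIs (decoupled,
  reproducible stages); at inference it consumes coarse-model ROIs, so a
  coarse miss cannot be recovered downstream.
* 3D context is ignored by design — the published method is slice-wise 2D.
* The smoothed Dice rewards exact empty-empty agreement; a single stray
  false-positive tumor pixel on a tumor-free slice drops that image's tumor
  Dice steeply. This is a property of the metric, reproduced faithfully.
* Phantom realism is deliberately limited (see above); no claim is made
  about full-scale CT benchmarks, which require the original data and
  GPU-scale training and are outside this package's acceptance surface.
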