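---
title: "Segmenting CSCR leakage from multimodal fundus pairs: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting CSCR leakage from multimodal fundus pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Chronic central serous chorioretinopathy (CSCR) is treated by focal laser
photocoagulation of the fluorescein *leakage point*, visible in fundus
angiography as a compact hyperfluorescent blob. Manual annotation of that
blob is slow; fully automatic detection is hard because the whole frame is
dominated by bright vessels and illumination gradients. `cscrseg`
implements a *semiautomatic* middle ground: the clinician supplies a
rectangular box around the suspicious area, and the package segments the
leakage inside it, exploiting a registered color fundus photograph of the
same eye to suppress the vessel distractors.

## Model and pipeline

**Vessel suppression (multimodal step).** Vessels have their best contrast
in the fundus green channel. After CLAHE, a truncated Laplacian of
Gaussian kernel

$$LoG(r,c) = -\frac{1}{\pi\sigma^4}\Big(1-\frac{r^2+c^2}{2\sigma^2}\Big)
  e^{-(r^2+c^2)/2\sigma^2}, \qquad \sigma = 3,\; (r,c)\in[-3,3]^2,$$

is correlated with the block. A practical point that shaped the design:
truncating this kernel at 7×7 clips most of its positive outer ring, so
the weight sum is about $-0.08$ rather than 0, and the response carries a
$-c\,\bar I(x)$ baseline on top of the second-derivative line term. Dark
vessels therefore surface in the *upper tail of the signed response* —
not in the magnitude — and the binarization thresholds the signed
response (`polarity = "dark"`). The threshold is Otsu's, floored by
median + 3·MAD: Otsu assumes a bimodal histogram and, on a block with few
vessel pixels, would otherwise split inside the background texture and
flood the mask. Components below 30 px are discarded, the mask is dilated
by 3 px (about half a major vessel's width, covering the partial-volume
halo that a smaller dilation leaves behind), and the masked angiography
pixels are filled by onion-peel propagation from the surround followed by
Jacobi smoothing sweeps — unmasked pixels are returned bit-exactly.

**Decomposition.** The inpainted block $G_P$ is rearranged into a patch
matrix (50×50 patches, stride 10, row-major vectorized columns, one
boundary-clamped extra origin per axis so every pixel is covered). Patching
makes the smooth background rank-deficient across columns while compact
targets stay sparse. The stable decomposition

$$\min_{L,S}\; \|L\|_* + \lambda\|S\|_1 + \tfrac{1}{2\mu}\|M - L - S\|_F^2$$

is solved by a monotone accelerated proximal gradient method: singular
value thresholding on $L$ (via the Gram-matrix eigendecomposition for
tall matrices), soft thresholding on $S$, Nesterov extrapolation through
the prox candidate, and an acceptance rule that keeps the recorded
objective non-increasing once $\mu$ is fixed. Stopping: relative candidate
change below `apg_tolerance` (default 1e-5) at the final $\mu$.

**Parameter defaults and why.**

* $\lambda = 1/\sqrt{\max(p,q)}$ — the standard robust-PCA weighting for a
  $p\times q$ observation; configurable and logged.
* $\mu$: continuation from $0.1\,\|M\|_2$, shrinking by 0.9 per iteration
  to a floor chosen so the per-iteration sparse threshold
  $\lambda\mu/2$ equals **2 estimated noise standard deviations**
  (Immerkær estimate on $G_P$). This sits deliberately between two
  textbook choices: a 3-sd floor leaves the sparse support patchy (target
  margins are truncated), while the stable-PCP scaling
  $\sqrt{2\max(p,q)}\,\sigma$ lets noise speckle into $S$ and creates
  spurious seed regions for the growing stage.
* Sparse-map binarization: the pipeline default is `"nonzero"` — at the
  optimum the $\ell_1$ prox has already zeroed every entry the model does
  not consider target, so only the 5-px minimum-area filter is needed on
  top. The stricter `"adaptive"` rule (mean + 2 sd of positive entries)
  remains available for truncated or very noisy solves; on converged
  solves it tends to keep only the strongest blob's peak and would starve
  the growing stage of seeds.
* Median (not mean) aggregation when folding patch-domain matrices back to
  the image: a pixel's value is unchanged when a minority of covering
  patches disagree.

**Region growing and fusion.** Each retained region contributes one seed:
the argmax of the sparse map inside the region (ties: topmost, then
leftmost), with the seed *value* read from the raw angiography block,
since growth runs there. A pixel is admitted iff
$|I(p) - I(\text{seed})| \le T$; comparing against the fixed seed
intensity (not a running mean) makes the result order-independent and
monotone in $T$. $T$ is a fraction of the normalized intensity range;
0.10–0.18 is the useful band and 0.18 the default. The fused mask is the
pixelwise union of the decomposition regions and the grown regions, so
fusion can only add pixels — that is the mechanism against the baseline's
undersegmentation. One safety valve: a grown region larger than
`max_growth_fraction` (default 25%) of the ROI is treated as a *failed*
growth and excluded. A leakage blob never fills the clinician's box; a
growth that large means the admission band reached the background (seeds
on mid-intensity inpainting remnants do this), and permissive-threshold
growing is known to fail in exactly this way. As a consequence, strict
mask monotonicity across $T$ holds for the successful growths only.

## The phantom generator

Clinical pairs are not redistributable, so validation runs on phantoms
emulating what the pipeline assumes:

* background: sum of 3 separable smooth profiles — exactly low-rank by
  construction (mean level 0.35, variation ±0.08);
* vessels: 6 random smooth strokes, 3–7 px wide, +0.30 contrast in
  angiography and −0.30 in the fundus green channel;
* leakage: 2–4 isotropic Gaussian blobs, σ = 6–12 px, peak contrast 0.45,
  added *only* to angiography (leakage is a fluorescein phenomenon);
  ground truth is the half-maximum support of the noiseless blob field —
  scale-free and analytically defined for Gaussian bumps;
* noise: i.i.d. Gaussian, sd 0.02, in both modalities;
* blob centers lie in a central "macular" disc (radius 70 px in the
  512×512 default) and at least two blob sigmas from any vessel, keeping
  the clinician's box compact and the ground truth unambiguous.

The ROI box for phantom experiments is the blob bounding box padded by
30 px, at least 100 px per side (`phantom_roi_box()`), emulating the
manual selection.

What the phantoms do **not** model: optic disc and macular pigmentation,
photometric differences between modalities, residual misregistration,
non-Gaussian leakage shapes, and vessels crossing the leakage site. A
pass on phantoms shows the machinery is implemented correctly and behaves
as designed where its assumptions hold; it does not certify clinical
performance.

## Numerical choices and degenerate inputs

* A constant ROI yields an empty region set without error (flat vessel
  response → empty mask; zero sparse map → no regions).
* CLAHE requires tile-divisible dimensions; blocks are replicate-padded
  and cropped back, and tiles shrink automatically for very small blocks.
  A flat field passes through unchanged.
* Connected components are 8-connected everywhere (4-connected labeling
  plus a diagonal union-find merge); diagonal blob boundaries do not
  fragment.
* SVD backend: LAPACK for small/near-square matrices, Gram-matrix
  eigendecomposition for tall ones (agreement to ~1e-13 on retained
  singular values).
* Region sorting: by area descending, ties by topmost-then-leftmost
  centroid, so outputs are deterministic.
* All randomness is confined to the phantom generator, which seeds a
  local RNG and restores the caller's state.

## Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` use 20 phantoms at the default
512×512 size (ROI blocks around 140–200 px, patch matrices of roughly
2500×120–250), the five-point threshold grid, a 2500×36 planted recovery
problem, and 20×20 instances for solver-vs-oracle comparisons. These sizes
keep a full run in the single-digit minutes on one CPU while leaving the
patch-image geometry at its standard 50/10 setting.

## Known limitations

* Inputs are assumed registered; there is no registration step, and
  vessel masks derived from the fundus are applied to the angiography
  as-is.
* The decomposition absorbs part of large blobs (FWHM comparable to the
  patch stride geometry) into the low-rank term; the growing stage exists
  to compensate, and the fused variant is the recommended output.
* The region-growing admission rule is seed-relative by design; a
  running-mean rule would adapt to gradients but lose order-independence
  and monotonicity in `T`.
* Thresholds above 0.18 are allowed but not recommended; growth failures
  become common (the safety valve then leaves the baseline mask).
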