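# cscrseg

Semiautomatic segmentation of the fluorescein **leakage point** of chronic
central serous chorioretinopathy (CSCR) from a registered multimodal fundus
pair — a fluorescein angiography frame plus a color fundus photograph of the
same eye. The leakage point is the target of focal laser photocoagulation,
so the package is aimed at retinal-imaging researchers who need pixel-level
leakage masks (and their coordinates) rather than manual annotations.

## Method

Within a clinician-drawn rectangular ROI, the pipeline

1. crops both modalities at the same coordinates (registration is assumed
   upstream);
2. detects retinal vessels on the CLAHE-enhanced fundus **green channel**
   with a truncated Laplacian of Gaussian filter
   (σ = 3, 7×7 support) and *inpaints* them out of the angiography block —
   bright vessels are the main distractor for leakage detection;
3. splits the inpainted block `G_P` into background, target and noise by a
   stable low-rank + sparse decomposition on its sliding-patch matrix
   (patch 50 × 50, stride 10):

   ```
   min  ‖L‖* + λ‖S‖₁ + (1/2μ)‖G_P − L − S‖F²,   λ = 1/√max(p, q)
   ```

   solved with a monotone accelerated proximal gradient method
   (singular-value thresholding on `L`, soft thresholding on `S`, Nesterov
   momentum, continuation on μ down to a noise-scaled floor);
4. folds the sparse part back to image frame (median over overlapping
   patches), binarizes it, and extracts 8-connected leakage regions sorted
   by area;
5. grows each region from the argmax of its sparse response on the raw
   angiography block (8-neighbor growth, admission `|I(p) − I(seed)| ≤ T`)
   and fuses the grown and decomposition masks by pixelwise union — region
   growing counteracts the decomposition's undersegmentation;
6. restores the result to full-image coordinates.

Four ablation variants are exposed: `LR` (decomposition only, no vessel
inpainting), `LRM` (the multimodal baseline), `LRM_to_R` (region growing
alone, seeded by the baseline) and `LRM_plus_R` (the fused joint
framework). Pixelwise sensitivity, F1, accuracy and specificity are
computed over the ROI against ground truth.

Because clinical CSCR pairs are not redistributable, the package ships a
synthetic phantom generator (`generate_phantom()`): a low-rank smooth
background, curvilinear vessels rendered bright in angiography and dark in
the fundus green channel, Gaussian leakage blobs present only in
angiography, i.i.d. sensor noise, and exact half-maximum blob masks as
ground truth.

## Worked example

```r
library(cscrseg)

ph  <- generate_phantom(phantom_spec(rng_seed = 42))
box <- phantom_roi_box(ph$truth, dim(ph$pair$angiography))
box
#> <roi_box> rows [223, 361) x cols [236, 349)  (138 x 113 px)

run <- run_pipeline(ph$pair, box, run_config(), variant = "LRM_plus_R")
run
#> <cscr_run> variant=LRM_plus_R, 2 region(s)
#> <biomarker_set> 2 region(s), 738 positive px in ROI
#>   #1 area=414 centroid=(42.7, 68.9)
#>   #2 area=324 centroid=(98.6, 38.0)

score_run(run, ph$truth)
#> sensitivity=0.8697  F1=0.8643  accuracy=0.9872  specificity=0.9930
```

The two regions are the leakage blobs, reported with ROI- and full-frame
coordinates (0-based); `run$biomarkers$full_mask` is the full-frame binary
mask and `run$report` a JSON-serializable provenance record (config,
solver diagnostics, per-stage timings, region table). On this phantom the
fused mask recovers 87% of the true leakage pixels at 99.3% specificity
within the ROI.

A thin command-line wrapper ships in `inst/scripts/cscrseg`
(`segment`, `simulate`, `evaluate`, `ablation` subcommands).

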