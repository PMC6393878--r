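# neuroseg

Fully automatic gray-matter / white-matter (and tumor) segmentation for
single axial T1-weighted brain MRI slices, with a synthetic brain-phantom
generator and a Dice-coefficient validation harness.

## Who this is for

Measuring cortical tissue from brain MRI — for atrophy, dementia staging, or
tumor delineation — starts with separating gray matter (GM), white matter
(WM) and cerebrospinal fluid (CSF). Manual tracing is slow and
error-prone; `neuroseg` automates the slice-level segmentation and ships the
machinery to validate it: exact-ground-truth phantoms, Dice reports with
five-number summaries, and an ablation table comparing the full pipeline
against plain clustering baselines.

## The method

On T1-weighted images tissue intensity is ordered CSF < GM < WM < skull.
The pipeline exploits that ordering with clustering bracketed by geometry:

1. **Skull stripping** — Otsu thresholding, then an elliptical Hough
   transform: every outer-contour pixel votes for candidate ellipses
   (center, semi-axes, rotation) passing within 1.5 px of it; the
   best-supported ellipse, shrunk inward by a margin, delimits the brain.
2. **Fuzzy c-means (FCM)** on the in-brain intensities `x_i`, minimizing

   `J_m = sum_i sum_j u_ij^m (x_i - c_j)^2,  m > 1`

   by alternating `c_j = sum_i u_ij^m x_i / sum_i u_ij^m` with
   `u_ij = 1 / sum_k (d_ij/d_ik)^(2/(m-1))`, `d_ij = |x_i - c_j|`.
   Three clusters map to CSF/GM/WM by center intensity. A hard k-means
   engine (nearest-center assignment + cluster means) is available for
   comparison.
3. **Connected-region postprocessing** — 8-connectivity component labeling;
   the largest component per tissue is the mask, overlaid on the original
   intensities, with boundary contours extracted.
4. **Validation** — Sørensen–Dice `2|A∩B| / (|A|+|B|)` between automatic
   and reference masks, per tissue and for the union GM ∪ WM ("total
   cortical matter").

Inputs: NIfTI-1, single-file DICOM, PNG, TIFF, JPEG (volumes reduced to one
axial slice). See the methods vignette (`vignettes/neuroseg-methods.Rmd`)
for parameter defaults, numerical choices, and what phantom tests do and do
not establish.

## Worked example

```r
library(neuroseg)

# a synthetic T1-like slice with known ground truth, 5% Gaussian noise
ph <- make_phantom(phantom_spec(noise_sigma = 0.05, seed = 0))
res <- segment_gm_wm(ph$slice)
res
#> <segmentation_result> GM 8689 px, WM 14200 px (strip: hough)
res$strip$ellipse
#> <ellipse> center (128.0, 128.0), semi-axes (110.0, 89.0), rotation 178.0 deg, votes 568
res$model
#> <cluster_model> fcm: N = 25363 pixels, c = 3, 9 iterations (converged)
#>   centers: 0.1508, 0.4524, 0.8018

dice_report(list(gm = res$gm_mask, wm = res$wm_mask),
            list(list(gm = ph$truth$gm_mask, wm = ph$truth$wm_mask)))
#> <dice_report>
#>  tissue n_pairs   mean sd    min     q1 median     q3    max
#>      gm       1 0.9994  0 0.9994 0.9994 0.9994 0.9994 0.9994
#>   total       1 0.9997  0 0.9997 0.9997 0.9997 0.9997 0.9997
#>      wm       1 0.9998  0 0.9998 0.9998 0.9998 0.9998 0.9998
```

Reading the output: the skull ellipse was recovered at the generating
geometry (semi-axes 110/90, here 110/89), the three FCM centers sit at the
phantom's CSF/GM/WM intensities (0.15/0.45/0.80), and both tissue masks
overlap ground truth with Dice ≥ 0.999.

## Command line

```sh
Rscript inst/cli/neuroseg segment --mode gm-wm --input slice.png --outdir out/
Rscript inst/cli/neuroseg phantom --n 5 --seed 0 --outdir phantoms/
Rscript inst/cli/neuroseg validate --auto out/ --ref expert1/,expert2/ --outdir report/
Rscript inst/cli/neuroseg compare --n 5 --seed 0 --outdir report/
```

`segment` writes `<stem>_gm_mask.png`, `<stem>_wm_mask.png`,
`<stem>_gm_region.png`, `<stem>_wm_region.png`, `<stem>_boundaries.png`
(contours over the original), a parameter record and a timestamped run log.
Exit codes: 0 ok, 2 usage error, 3 skull-detection failure, 4 degenerate
clustering.

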