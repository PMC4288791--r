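# gbsi

Longitudinal atrophy measurement for brain MRI by the generalized boundary
shift integral.

## What this is for

Rates of whole-brain and hippocampal volume loss from serial T1-weighted
MRI are standard biomarkers of neurodegenerative disease progression and
common outcome measures in clinical trials. The boundary shift integral
(BSI) estimates the volume change between two co-registered scans directly
from clipped intensity differences over a region straddling the structure
boundary, which is substantially more precise than subtracting two
independently segmented volumes.

`gbsi` is for image-analysis researchers and trialists who have registered
scan pairs with probabilistic segmentations and want atrophy rates and the
trial sample sizes they imply. It implements:

* **gBSI** — the generalized BSI. The boundary region is the probabilistic
  exclusive OR of the two time points' segmentations,

  pXOR(A, B) = A·(1−B) + (1−A)·B − A·(1−B)·(1−A)·B,

  rescaled by an adaptive gain κ (the mean of the strictly positive pXOR
  voxels): weights are pXOR/κ below κ and 1 at or above it. The integral is

  BSI = D · Σ R·(clip(I_A) − clip(I_B)),

  with D the voxel volume (mm³) and clip the linear rescaling into the
  automatically selected intensity window [mean(CSF)+sd(CSF),
  mean(GM)−sd(GM)]. With κ = 1 and binary masks, gBSI reverts exactly to
  the classic binary-XOR formulation.
* **KN-BSI** — the binary-XOR region (dilated union minus eroded
  intersection of the 0.5-binarized masks) with k-means tissue
  normalization; and **pBSI₁ / pBSI_γ** — the fuzzy thresholded-union /
  thresholded-intersection regions, for comparison studies.
* **Double intensity window** for structures bordered by both CSF and
  white matter (hippocampus): the GM–WM-window integral enters with
  opposite sign so loss counts positively at both borders.
* **Symmetric differential bias correction** — median-filtered
  log-intensity difference (kernel radius 5), split evenly between the two
  time points.
* **Trial statistics** — sample size per arm
  (0.841 + 1.96)²·2σ²/Δ² for 80% power at 5% two-sided significance,
  with Δ = 25% of progression (alone, or in excess of normal aging) and
  bias-corrected bootstrap confidence intervals.
* **Synthetic phantoms** — nested-ellipsoid scan pairs with analytically
  known volume change, for end-to-end validation without any imaging data.

Inputs are NIfTI-1/2 volumes (optionally gzipped) already resampled to a
common half-way space, each with a probabilistic mask in [0, 1] on the same
grid. Registration and segmentation are out of scope by design.

## Worked example

Generate a phantom with exactly 2% annual volume loss and measure it:

```r
library(gbsi)

spec <- phantom_spec(grid_shape = c(64, 64, 64), voxel_size = 1.5,
                     atrophy_fraction = 0.02)
ph <- make_phantom(spec)
res <- run_bsi(ph$pair, pipeline_config(dbc = FALSE))
res
#> <bsi_result> variant pxor_gbsi
#>   BSI:  2601.04 mm^3
#>   PBVC: 2.0571 %/yr over 1 yr
#>   baseline volume: 126441 mm^3, 39272 region voxels
#>   kappa: 0.10381
#>   window CSF-GM: [58.976, 100.05]
```

The measured PBVC of 2.06 %/yr recovers the true 2 %/yr loss to within 3%
relative error at this coarse 1.5 mm resolution; κ ≈ 0.10 is the mean
disagreement of the two probabilistic masks, and the window [59, 100] is
the automatically selected CSF–GM intensity band the integral operates in.

Sample sizes per arm for a trial detecting a 25% reduction in progression,
from published whole-brain PBVC group statistics (AD mean 1.40, SD 0.77;
controls mean 0.56 %/yr):

```r
ad <- group_stats("AD", mean_pbvc = 1.40, sd_pbvc = 0.77)
controls <- group_stats("controls", mean_pbvc = 0.56, sd_pbvc = 0.60)
estimate_sample_size(ad)
#> <sample_size_result> n per arm = 76 (raw 75.9454)
#>   delta = 0.35 %/yr, sigma = 0.77 %/yr
estimate_sample_size(ad, controls)
#> <sample_size_result> n per arm = 211 (raw 210.959), controlling for normal aging
#>   delta = 0.21 %/yr, sigma = 0.77 %/yr
```

76 subjects per arm suffice when the endpoint is the AD atrophy rate
itself; 211 when the effect is the excess over normal aging (the effect
shrinks, the patient-group SD stays).

## Command line

A thin Rscript wrapper with three subcommands lives at
`inst/cli/gbsi.R` (after installation:
`system.file("cli", "gbsi.R", package = "gbsi")`):

```sh
gbsi.R bsi --baseline b.nii.gz --repeat r.nii.gz \
       --baseline-mask bm.nii.gz --repeat-mask rm.nii.gz \
       --interval 1.0 --report report.json
gbsi.R phantom --dir out/ --atrophy 0.02 --seed 7
gbsi.R samplesize --mean-ad 1.40 --sd-ad 0.77 --mean-control 0.56 --sd-control 0.60
```

Pipeline parameters come from a flat `key = value` config file
(`write_config()` / `read_config()`); every report embeds the full
effective parameter set.

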