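# atstseg

Semi-supervised segmentation of infected lung regions (ground-glass opacity
and consolidation) in chest CT, built around three ideas:

1. **Hounsfield-unit pseudo-labels.** Lesional lung tissue falls in a known
   attenuation band. Thresholding HU inside the lung mask,

   `pseudo(v) = 1  iff  lung(v) = 1  and  -750 <= HU(v) <= 50`,

   yields zero-cost but noisy lesion labels: GGO occupies roughly
   [-750, -300] HU, consolidation [-300, 50] HU, and some healthy dense
   tissue (vessels, airway walls) falls in the same band.

2. **A dual-branch (clean/noisy) network.** Two structurally identical
   encoder–decoder (U-Net style) branches are trained jointly: the clean
   branch on expert labels plus pseudo-labels,
   `L_clean = L_mseg + λ·L_pseg-clean`, the noisy branch on pseudo-labelled
   images only, `L_noisy = λ·L_pseg-noisy`, where every stream loss is
   `L_seg = 0.5·(L_dice + L_BCE)`. The branches are coupled by an adaptive
   exponential moving average that blends clean weights into the noisy
   branch,

   `θ'_t = ε·θ'_{t−1} + (1−ε)·θ_t`,  `ε(i) = 1 − 0.2·exp(−8i/iters)`,

   so ε starts at 0.8 (fast transfer) and approaches 1 (late-training
   stability).

3. **Automatic target switching.** Each pseudo-labelled image is scored by

   `S = LEV(gt_pseudo, p_clean) / exp(div(gt_pseudo, p_noisy))`,

   the Lovász extension of the Jaccard loss of the clean prediction against
   the pseudo-label, discounted by a symmetric Bernoulli KL divergence. Once
   `S − τ >= 0` — τ being the sliding median of recent scores over a
   100-iteration window — the noisy branch's supervision target switches
   from the HU pseudo-label to the binarized clean-branch prediction, so
   late training stops learning the pseudo-labels' noise.

Evaluation uses the Dice similarity coefficient
`DSC = 2|A∩B| / (|A|+|B|) × 100` and the 95th-percentile Hausdorff distance
(pixels). The package also quantifies infection burden (lung and lesion
volumes in ml, infection ratio, GGO vs consolidation split), reads NIfTI and
uncompressed DICOM series, and ships a synthetic CT phantom generator so the
entire pipeline is testable without any data download. The convolutional
network engine (single-precision im2col/GEMM with exact backprop) is built
into the package.

## Worked example

```r
library(atstseg)

ph <- generate_phantom(phantom_spec(seed = 5))   # 64x64x8 CT phantom
ph$volume
#> <hu_volume> 64x64x8 voxels, spacing 1x1x5 mm, HU range [-1077, 146]

pl <- generate_pseudolabel(ph$volume, ph$lung)   # Hu_[-750,50] inside lung
pl
#> <label_mask role=pseudo> 64x64x8 voxels, 400 foreground
round(pseudo_label_noise_rate(ph$lesion, pl), 3)
#>   fp   fn
#> 0.37 0.00
```

37% of the pseudo-label voxels are false positives (vessel-like distractors
inside the lesion HU band) — exactly the noise the target-switching
mechanism is designed to outgrow — while no true lesion voxel is missed.

```r
st  <- classify_lesion_subtypes(ph$volume, ph$lesion)
quantify_infection(ph$lung, ph$lesion, st, spacing = ph$volume$spacing)
#>  lung_volume_ml lesion_volume_ml infection_ratio ggo_volume_ml
#>           35.36             1.26      0.03563348          0.74
#>  consolidation_volume_ml n_outside_lung empty_lung
#>                     0.52              0      FALSE

evaluate_benchmark(list(pl), list(ph$lesion), ids = "phantom05")
#>        case      dsc    hd95
#> 1 phantom05 77.30061 8.87623
#> aggregate: DSC 77.30 +/- 0.00 %, HD95 8.88 +/- 0.00 px
```

The phantom carries 1.26 ml of lesion in 35.4 ml of lung (infection ratio
3.6%), split into 0.74 ml GGO and 0.52 ml consolidation; the raw pseudo-label
scores DSC 77.3 against the truth, which is the noise floor the trained
model has to beat.

Training the full dual-branch model and the ablation arms on a phantom
benchmark (20 expert-labelled + 40 pseudo-labelled cases):

```r
res <- ablation_benchmark(seeds = 1:5)   # unet / adaptive_ema / atst
with(res, tapply(median_dsc, arm, median))
```

which reproduces, at phantom scale, the qualitative ordering
supervised-only ≤ adaptive EMA ≤ full target switching.

A command-line interface wraps the same functions:

```sh
atstseg synth --n 10 --out data/
atstseg pseudolabel --in case_ct.nii.gz --lung case_lung.nii.gz --out pseudo.nii.gz
atstseg train --data data/ --out runs/exp1 --seed 1
atstseg predict --model runs/exp1/model.rds --in case_ct.nii.gz --lung case_lung.nii.gz --out pred.nii.gz
atstseg quantify --in case_ct.nii.gz --lung case_lung.nii.gz --lesion pred.nii.gz --report report.json
atstseg evaluate --pred preds/ --truth truths/ --report metrics.csv
```

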