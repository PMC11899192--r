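# fibmorph

Cross-sectional morphometry of the fibular cortical bone from MR images and
binary segmentation masks, with a synthetic phantom/cohort generator and the
study-level statistical battery.

## The problem

Bone loss in the lower extremity — wall thinning and mineral-density
decrease — can be quantified from axial T2-weighted MRI, where the fibular
shaft appears as a hypointense ring of compact bone around bright marrow.
Given a traced bone mask, this package measures, per cross-section:

- **BA**, bone area (mm²): foreground pixels × pixel area;
- **CL**, centerline length (mm): the physical length of the one-pixel-wide
  medial-axis loop through the cortical wall, obtained by topology-preserving
  thinning, spur pruning and longest-cycle extraction;
- **BT**, wall thickness (mm): the ring-model estimate
  `BT = BA / CL` — for an annulus this equals `(D_out − D_in) / 2` exactly;
- **g-ratio**: the inner-to-outer diameter ratio
  `g = (CL/π − BT) / (CL/π + BT) = D_in / D_out`, a relative-thinning index
  analogous to the axonal myelination g-ratio;
- **MPI**, mean pixel intensity of the bone mask after robust affine-invariant
  slice normalization — an index of mineral-density loss;
- **BMA**, marrow area (mm²).

Subject values average the central seven slices of a nine-slice stack
(`BT` is the mean of per-slice `BA/CL`). The statistics layer provides the
study-style analyses: pooled-variance two-sample t-tests, Pearson
correlations with least-squares lines, muscle-fat-infiltration (MFI) class
contrasts, segmentation-reproducibility CVs, and a measurement-noise
robustness check. Because the cohort MRI that motivates these analyses is
not publicly deposited, validation is built on synthetic annular phantoms
with analytic ground truth and simulated cohorts with known effect
structure — both first-class, tested parts of the package.

Intended users: image-analysis researchers working on cortical bone
morphometry who need a tested, reproducible measurement chain, and
methodologists who want the phantom/cohort machinery to stress their own
pipelines.

## Worked example

```r
library(fibmorph)

# a clean annulus phantom at the native 0.7 mm resolution
ph <- make_annulus_phantom(phantom_spec(outer_diameter = 10.9,
                                        wall_thickness = 2.7))
slice_morphometry(ph$image, ph$bone, ph$marrow)
#>   slice_index   BA    CL    BT centerline_diameter D_out D_in      g    MPI
#> 1           1 68.6 27.04 2.537               8.607 11.14 6.07 0.5447 0.1489
#>     BMA is_closed flagged
#> 1 25.48      TRUE   FALSE
```

The true values are BT = 2.7 mm, g = 5.5/10.9 ≈ 0.505, BA ≈ 69.6 mm²: at
0.7 mm pixels the measured thickness is within a quarter pixel and g within
0.04. A full subject — nine jittered slices, triangular deformation,
noise — and a group comparison:

```r
set.seed(42)
st <- make_phantom_stack(phantom_spec(outer_diameter = 10.9, wall_thickness = 2.7,
                                      noise_sd = 0.02,
                                      deformation_harmonics = list(c(3, 0.05, 1.1))),
                         n_slices = 9, subject_id = "demo")
subject_morphometry(st)
#> <subject_morphometry> demo
#>   BT 2.63 mm | BA 71.2 mm^2 | CL 27.1 mm | g 0.533
#>   MPI 0.194 | BMA 24.3 mm^2 | 7 slice(s)

two_sample_ttest(c(2.1, 1.9, 2.4, 2.0), c(2.9, 3.1, 2.6, 3.2),
                 labels = c("F", "M"), variable = "BT")
#> BT: F (n=4, 2.1 +/- 0.216) vs M (n=4, 2.95 +/- 0.265): t=-4.977, p=0.002509 *
```

An end-to-end synthetic study — image-mode cohort generation, per-subject
measurement, the full analysis battery, CSV/JSON outputs stamped with the
config hash — is one call:

```r
study <- run_synthetic_study(study_config(mode = "image", seed = 1,
                                          out_dir = "study_out"))
summary(study)
```

A thin command-line wrapper over the same functions lives at
`inst/cli/fibmorph.R` (subcommands `phantom`, `cohort`, `measure`, `stats`,
`study`).

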