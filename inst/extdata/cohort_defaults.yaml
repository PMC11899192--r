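# Default cohort parameters for the synthetic fibula study.
#
# Group means/SDs, group sizes and age ranges emulate the published group
# statistics of an adult 7T MRI fibular morphometry cohort (107 subjects,
# 43F/64M, split at age 50): these are literature-derived defaults describing the
# conditions the simulator emulates, not ground truth the pipeline is meant
# to reproduce. MFI class probabilities, SFT distribution, age slopes and
# rendering settings are not printed in that literature and are realistic
# choices fixed here once (see the methods vignette).
groups:
  F_le50:
    "n": 17
    sex: "F"
    age_min: 15.0
    age_max: 50.0
    BT: {mean: 2.9, sd: 0.5}
    BA: {mean: 67.9, sd: 12.6}
    g: {mean: 0.37, sd: 0.13}
    MPI: {mean: 0.12, sd: 0.04}
    mfi_probs: {normal: 0.50, mild: 0.35, moderate: 0.15}
  M_le50:
    "n": 13
    sex: "M"
    age_min: 11.0
    age_max: 50.0
    BT: {mean: 2.9, sd: 0.5}
    BA: {mean: 71.7, sd: 7.7}
    g: {mean: 0.42, sd: 0.16}
    MPI: {mean: 0.12, sd: 0.04}
    mfi_probs: {normal: 0.50, mild: 0.35, moderate: 0.15}
  F_gt50:
    "n": 26
    sex: "F"
    age_min: 50.0
    age_max: 78.0
    BT: {mean: 2.0, sd: 0.5}
    BA: {mean: 58.6, sd: 15.0}
    g: {mean: 0.61, sd: 0.13}
    MPI: {mean: 0.17, sd: 0.05}
    mfi_probs: {normal: 0.25, mild: 0.45, moderate: 0.30}
  M_gt50:
    "n": 51
    sex: "M"
    age_min: 50.0
    age_max: 79.0
    BT: {mean: 2.9, sd: 0.6}
    BA: {mean: 85.1, sd: 16.9}
    g: {mean: 0.49, sd: 0.11}
    MPI: {mean: 0.12, sd: 0.05}
    mfi_probs: {normal: 0.25, mild: 0.45, moderate: 0.30}
age_slopes:
  bt: {F: -0.02, M: 0.0}      # mm / year, applied about the group age midpoint
  mpi: {F: 0.0012, M: 0.0004} # 1 / year
bmi:
  F: {mean: 30.3, sd: 5.7}
  M: {mean: 28.4, sd: 4.4}
sft: {mean: 6.0, sd: 2.5}     # mm
image:
  pixel_spacing: 0.7          # mm, in-plane
  grid_size: 64
  supersample_factor: 8
  noise_sd: 0.02
  deformation_amplitude: 0.05 # order-3 harmonic (triangular periosteum)
  jitter: 0.02                # max fractional slice-to-slice geometry change
  n_slices: 9
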