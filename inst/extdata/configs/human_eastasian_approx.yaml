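# SYNTHETIC, APPROXIMATE piecewise stand-in for an East-Asian-like human
# demographic history: out-of-Africa bottleneck followed by a second
# (Europe-Asia split) bottleneck about 2,000 generations ago and recent
# growth. The published human models this emulates are defined only in
# supplementary material we do not reproduce; these epochs are illustrative
# round numbers, intended as an editable template, and are NOT calibrated
# to any published inference. Edit the epochs to use a real model.
label: human_eastasian_approx_synthetic
seed: 1
alpha: 0.05
n_reps: 200
n_null: 1000
n_null_bin: 200
sample_n: 120
ehh_distance: 20000
model:
  label: east asian (approximate, synthetic)
  reference_N: 10000
  time_unit: generations
  epochs:
    - {t_start: 0, size: 30000}     # recent growth
    - {t_start: 1000, size: 5000}   # post-split recovery
    - {t_start: 2000, size: 600}    # Europe-Asia split bottleneck
    - {t_start: 2500, size: 10000}  # out-of-Africa ancestral
    - {t_start: 4000, size: 1500}   # out-of-Africa bottleneck
    - {t_start: 4500, size: 14000}  # African ancestral
cells:
  - {name: sdn_onset_2000, mode: SDN, s: 0.005, t_age: 2000, stats: [D, H], region: sfs}
  - {name: ssv_onset_2000, mode: SSV, s: 0.005, p1: 0.1, t_sel: 2000, stats: [D, H], region: sfs}
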