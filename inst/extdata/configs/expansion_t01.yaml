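# Expansion model 1 of the basic grid: current size 10x the ancestral
# N1 = 4,770, expansion at t1 = 0.1 N generations (reference_N = 5,000,
# so 500 generations); same long-term effective size as the constant model.
# The cells contrast power and FPR when the null ignores the expansion
# (null_model: standard neutral N = 5,000) with the data-generating truth.
label: expansion_t01
seed: 1
alpha: 0.05
n_reps: 200
n_null: 1000
n_null_bin: 200
sample_n: 120
ehh_distance: 25000
model:
  label: expansion N1=4770 t1=0.1
  reference_N: 5000
  time_unit: scaled_N
  epochs:
    - {t_start: 0, size: 47700}
    - {t_start: 0.1, size: 4770}
null_model:
  label: standard neutral N=5000
  reference_N: 5000
  time_unit: generations
  epochs:
    - {t_start: 0, size: 5000}
cells:
  - {name: fpr_sfs, mode: NEUTRAL, stats: [D, H], region: sfs}
  - {name: sdn_age_1000, mode: SDN, s: 0.005, t_age: 1000, stats: [D, H], region: sfs}
  - {name: sdn_age_2500, mode: SDN, s: 0.005, t_age: 2500, stats: [D, H], region: sfs}
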