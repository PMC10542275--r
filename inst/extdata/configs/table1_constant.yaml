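# Constant-population columns of the four-test power table:
# N = 10,000 (diploid), selection onset 2,000 generations before present,
# s = 0.005 (h = 0.5), 120 sampled chromosomes, alpha = 0.05 one-sided,
# matched constant-model null. SDN = selection on a de novo mutation;
# SSV = selection on standing variation starting from frequency 0.1.
# SFS statistics use 10-kb regions with a central target; haplotype
# statistics use 500-kb regions with the target at the edge.
label: table1_constant
seed: 1
alpha: 0.05
n_reps: 200
n_null: 1000
n_null_bin: 200
sample_n: 120
ehh_distance: 25000
model:
  label: constant N=10000
  reference_N: 10000
  time_unit: generations
  epochs:
    - {t_start: 0, size: 10000}
cells:
  - {name: constant_SDN, mode: SDN, s: 0.005, t_age: 2000, stats: [D, H], region: sfs}
  - {name: constant_SDN, mode: SDN, s: 0.005, t_age: 2000, stats: [rEHH, iHS], region: hap}
  - {name: constant_SSV, mode: SSV, s: 0.005, p1: 0.1, t_sel: 2000, stats: [D, H], region: sfs}
  - {name: constant_SSV, mode: SSV, s: 0.005, p1: 0.1, t_sel: 2000, stats: [rEHH, iHS], region: hap}
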