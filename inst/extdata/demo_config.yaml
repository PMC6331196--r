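# Demonstration cross: IPO323 x IPO94269 under the female-restricted drive.
# chr18 and chr20 are unpaired (present only in IPO323); the other six
# supernumerary chromosomes are paired.
parents:
  - name: IPO323
    mating_type: mat1-1
    chromosomes: [chr14, chr15, chr16, chr17, chr18, chr19, chr20, chr21]
    mito: mtIPO323
    density: 1.0e+7
  - name: IPO94269
    mating_type: mat1-2
    chromosomes: [chr14, chr15, chr16, chr17, chr19, chr21]
    mito: mtIPO94269
    density: 1.0e+7
mechanism: female_drive
loss_rate: 0.0
nondisjunction_rate: 0.0
n_asci: 100
seed: 42
snp:
  enabled: true
  n_snps: 2000
  coverage_mean: 12
  coverage_dispersion: 0.8
  dropout_rate: 0.02
  filter_mode: min_cov_any
  threshold: 8
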