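n_families: 20
loci: [A, B, C]
seed: 7
n_alleles_per_locus: 12
dirichlet_concentration: 1.0
methods:
  - label: cleanTyper
    miscall_rate: 0.0
    homozygote_inflation_rate: 0.0
    output_resolution: 4
  - label: noisyTyper
    miscall_rate: 0.05
    serotype_preserving_fraction: 0.5
    homozygote_inflation_rate: 0.02
    output_resolution: 8
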