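name: hblup_missing_half
# Single-step experiment: a related discovery set in which a random subset
# is ungenotyped but phenotyped. PRS and GBLUP use the genotyped discovery
# individuals only; HBLUP additionally absorbs the ungenotyped relatives
# through the pedigree block of the H matrix.
simulation:
  n_families: 400
  sibship_size: 4
  n_generations: 2
  n_snps: 1000
  maf_range: [0.1, 0.5]
  h2: 0.5
  f2: 0.0
  causal_fraction: 1.0
  seed: 7
designs:
  - label: missing_half
    degree: "1"
    n_discovery: 2000
    n_target: 400
    seed: 7
    n_ungenotyped: 1200
analysis:
  - prs
  - gblup
  - hblup
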