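name: small_deg1_vs_unrelated
# Desk-scale contrast of a small design built from first-degree relative
# groups against one built from mutually unrelated founders, PRS analysis.
simulation:
  n_families: 120
  sibship_size: 3
  n_generations: 2
  n_snps: 600
  maf_range: [0.1, 0.5]
  h2: 0.5
  f2: 0.1
  causal_fraction: 1.0
  seed: 42
designs:
  - label: unrelated
    degree: unrelated
    n_discovery: 150
    n_target: 50
    seed: 11
  - label: deg1
    degree: "1"
    n_discovery: 150
    n_target: 50
    seed: 11
analysis:
  - prs
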