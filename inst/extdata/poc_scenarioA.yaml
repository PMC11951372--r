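# Proof-of-concept scenario A: three loci without CNV alleles, strong
# allele effects, no haplotype effects.  LD is placed on the pairs A-F,
# B-G and E-H; allelic ambiguity between A/B, E/F and G/H.  Levels use
# the standardized 0-1 scale (0 none, 0.4 medium, 0.8 high).
af:
  g1: {NEG1: 0.25, A: 0.45, B: 0.30}
  g2: {NEG2: 0.35, E: 0.35, F: 0.30}
  g3: {NEG3: 0.70, G: 0.15, H: 0.15}
effects:
  NEG1: 0.0
  A: 5.0
  B: -5.0
  NEG2: 0.0
  E: 3.5
  F: -3.5
  NEG3: 0.0
  G: 2.5
  H: -2.5
ld_pairs:
  - [A, F]
  - [B, G]
  - [E, H]
ld_level: 0.4
ambiguity_groups:
  - [A, B]
  - [E, F]
  - [G, H]
ambiguity_level: 0.4
hap_effects: [A-E, F-H]
use_hap_effects: false
family: gaussian
effect_multiplier: 3      # the proof-of-concept multiplies or divides by 3
N: 2000
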