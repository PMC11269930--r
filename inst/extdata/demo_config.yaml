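# Demo pipeline configuration: a small four-species design with one
# introgression pulse (P3 -> P2) and two F1 hybrids between P1 and P3.
seed: 42
simulate:
  species_tree: "(((P1:1,P2:1):1,P3:2):2,O:4);"
  samples_per_species:
    P1: 2
    P2: 2
    P3: 2
    O: 2
  mut_rate: 2.0e-5
  window_length: 10000
  window_spacing: 100000
  chromosomes:
    - {chrom: chr1, length: 4000000, is_z: false}
    - {chrom: chr2, length: 4000000, is_z: false}
    - {chrom: chr3, length: 4000000, is_z: false}
    - {chrom: chrZ, length: 2000000, is_z: true}
  alpha: 2
  r_min: 0.1
  z_scale: 0.1
  pulses:
    - {time: 0.5, donor: P3, recipient: P2, gamma: 0.15}
  hybrids:
    - {parent_a: P1, parent_b: P3, generation: F1, count: 2, error_rate: 0.01}
filter:
  min_maf: 0.03
  max_missing: 0.10
dstat:
  outgroup: O
  block_size: 1000000
aims:
  group_a: P1
  group_b: P3
  min_per_group: 2
  min_aims: 25
quartets:
  mode: SCALED_FOLDED
concord:
  max_trees: 100
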