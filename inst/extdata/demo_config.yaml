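# Small synthetic demo: 2 regions x 8 samples, 10 species with fully
# region-private haplotypes. Runs in seconds.
synth:
  n_regions: 2
  samples_per_region: 8
  n_species: 10
  structure_strength: 1
  detection_prob: 1
  seed: 5
params:
  permutations: 199
  scrambles: 10
  kmeans_k: 2
  seed: 5
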