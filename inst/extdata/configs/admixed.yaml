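# dispersed, non-homogenized repeats plus a late hybridization between two
# non-sister lineages with block-wise mosaic retention
seed: 11
hybridization:
- parents: [st1, st3]
  time: 0.75
  retention: 0.5
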