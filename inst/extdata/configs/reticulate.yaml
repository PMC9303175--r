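# reticulation experiment: homogenizing background (treelike baseline) with
# a very late hybridization whose repeats recombine while the hybrid genome
# stabilizes; compare against the same config without the hybridization event
seed: 11
placement: arrayed
homogenization_rate: 100
birth_rate: 0.1
death_rate: 0.05
truncation_rate: 0.02
hybrid_repeat_recomb: 0.6
hybridization:
- parents: [st1, st3]
  time: 0.795
  retention: 0.5
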