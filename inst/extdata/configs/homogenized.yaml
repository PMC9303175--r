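# concerted-evolution regime: tandem arrays with gene conversion fast enough
# to dominate the mutation input (h >> mu * L)
seed: 11
placement: arrayed
homogenization_rate: 100
birth_rate: 0.1
death_rate: 0.05
truncation_rate: 0.02
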