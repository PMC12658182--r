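# Run configuration for the bundled synthetic cohort.
tolerance: 0
ambiguity_tolerance: 300000
cnloh_mode: second_hit
lineage: false
clone_cap: 64
resolution_cap: 10000
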