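source	n_motifs
histone_mod_datasets	150
pseudostate_datasets	103
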