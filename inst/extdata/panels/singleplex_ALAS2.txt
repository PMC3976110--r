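panel: singleplex_ALAS2
melt_range: 65 90
grid_step: 0.1

marker: ALAS2
fluid: blood
tm_mean: 85.8
window: 85.6 86
required_window: 1
amplicon_size: 136
primer_fwd: TGTGTCCGTCTGGTGTAGTA
primer_rev: AAACTTACTGGTGCCTGAGA
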