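panel: singleplex_TGM4
melt_range: 65 90
grid_step: 0.1

marker: TGM4
fluid: semen
tm_mean: 82.3
window: 82.2 82.4
required_window: 1
amplicon_size: 164
primer_fwd: ATGGTGTAAAGAGGACATGGTT
primer_rev: GGGAAATGCAGCAGTCCAG
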