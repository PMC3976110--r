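panel: duplex_saliva_semen
melt_range: 65 90
grid_step: 0.1

marker: HTN3
fluid: saliva
tm_mean: 76.3
window: 75.9 76.7
required_window: 1
amplicon_size: 134
primer_fwd: GCAAAGAGACATCATGGGTA
primer_rev: GCCAGTCAAACCTCCATAATC

marker: TGM4
fluid: semen
tm_mean: 82.3
window: 82.2 82.4
required_window: 1
amplicon_size: 164
primer_fwd: ATGGTGTAAAGAGGACATGGTT
primer_rev: GGGAAATGCAGCAGTCCAG
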