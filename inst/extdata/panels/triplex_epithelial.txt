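panel: triplex_epithelial
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

marker: IL19
fluid: vaginal
tm_mean: 81.5
window: 81.3 81.7
required_window: 1
amplicon_size: 189
primer_fwd: AACCACGGTCTCAGGAGATG
primer_rev: GAACGCCAGGAGGTTCTTG

marker: IL1F7
fluid: skin
tm_mean: 83.2
window: 82.9 83.5
required_window: 1
amplicon_size: 92
primer_fwd: CCAGTGCTGCTTAGAAGACC
primer_rev: TCACCTTTGGACTTGTGTGAA
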