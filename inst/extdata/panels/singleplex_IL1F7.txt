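panel: singleplex_IL1F7
melt_range: 65 90
grid_step: 0.1

marker: IL1F7
fluid: skin
tm_mean: 83.2
window: 82.9 83.5
required_window: 1
amplicon_size: 92
primer_fwd: CCAGTGCTGCTTAGAAGACC
primer_rev: TCACCTTTGGACTTGTGTGAA
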