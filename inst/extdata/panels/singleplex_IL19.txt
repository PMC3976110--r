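panel: singleplex_IL19
melt_range: 65 90
grid_step: 0.1

marker: IL19
fluid: vaginal
tm_mean: 81.5
window: 81.3 81.7
required_window: 1
amplicon_size: 189
primer_fwd: AACCACGGTCTCAGGAGATG
primer_rev: GAACGCCAGGAGGTTCTTG
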