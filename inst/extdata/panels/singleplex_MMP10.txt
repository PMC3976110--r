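panel: singleplex_MMP10
melt_range: 65 90
grid_step: 0.1

marker: MMP10
fluid: menstrual
tm_mean: 82.2 83.5
window: 81.8 82.7
window: 83 84
required_window: 1
amplicon_size: 227
primer_fwd: ACAGGGAAGCTAGACACTGA
primer_rev: CTGGAGAATGTGAGTGGAGT
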