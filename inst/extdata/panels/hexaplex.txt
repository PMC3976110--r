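panel: hexaplex
melt_range: 73 90
grid_step: 0.1
dna_window: 80.2 80.9

marker: HTN3
fluid: saliva
tm_mean: 76.6
window: 76 77.2
required_window: 1
amplicon_size: 134
primer_fwd: GCAAAGAGACATCATGGGTA
primer_rev: GCCAGTCAAACCTCCATAATC

marker: IL19
fluid: vaginal
tm_mean: 78.6
window: 78 79.2
required_window: 1
amplicon_size: 109
primer_fwd: AACCACGGTCTCAGGAGATG
primer_rev: TGACATTTGGGAAGGTGTCC

marker: MMP10
fluid: menstrual
tm_mean: 81.9
window: 81.5 82.3
required_window: 1
amplicon_size: 178
primer_fwd: GGGGGTGACGTTGGTCACTTCAGCTC
primer_rev: GGGGGCTGGAGAATGTGAGTGGAGT

marker: TGM4
fluid: semen
tm_mean: 82.7
window: 82.4 83
required_window: 1
amplicon_size: 164
primer_fwd: ATGGTGTAAAGAGGACATGGTT
primer_rev: GGGAAATGCAGCAGTCCAG

marker: CCL27
fluid: skin
tm_mean: 84.9
window: 84.8 84.9
required_window: 1
amplicon_size: 142
primer_fwd: AGCACTGCCTGCTGTACTCA
primer_rev: AGATGCTGCGTTGAGCCA

marker: ALAS2
fluid: blood
tm_mean: 86.8
window: 86.6 86.9
required_window: 1
amplicon_size: 222
primer_fwd: TGTGTCCGTCTGGTGTAGTA
primer_rev: GAGTCATTGGCAACAAAGCA
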