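category	percent
known_mirna	56.36
star_mirna	1.02
ortholog_exact	11.07
ortholog_mismatch	0.09
degraded_mrna	1.03
repeat	6.71
trna_rrna_snrna	18.57
residual_unannotated	5.16
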