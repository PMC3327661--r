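quantity	value
detected_mirnas	186
de_mirnas	170
known_chicken_mirnas	122
unannotated_star_strands	31
ortholog_exact_hsa	29
ortholog_exact_tgu	2
ortholog_mismatch	4
genome_or_ortholog_mapped_percent	98.45
avian_candidate_matures	6
avian_candidate_hairpins	5
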