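name	hairpin_id	arm	is_star	annotated_species
gga-miR-1451	hp-1451-synth	five_prime	FALSE	gga
gga-miR-1559	hp-1559-synth	five_prime	FALSE	gga
gga-miR-2131	hp-2131-synth	five_prime	FALSE	gga
gga-miR-2131*	hp-2131-synth	three_prime	TRUE	gga
gga-miR-2954	hp-2954-1-synth	five_prime	FALSE	gga,tgu
gga-miR-2954*	hp-2954-2-synth	three_prime	TRUE	gga,tgu
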