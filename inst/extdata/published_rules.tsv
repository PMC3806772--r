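rule_id	conditions	class	support	correct
rule_4	pfam_fraction_affected <= 0; in_repeat == FALSE; in_disorder == TRUE	neutral	317	291
rule_5	pfam_fraction_affected <= 0; in_repeat == FALSE; in_disorder == FALSE; left_base_conservation <= 1.405	neutral	82	59
rule_10	pfam_fraction_affected > 0; in_disorder == FALSE	damaging	284	254
default_repeat	pfam_fraction_affected <= 0; in_repeat == TRUE	damaging	2	1
default_conserved	pfam_fraction_affected <= 0; in_repeat == FALSE; in_disorder == FALSE; left_base_conservation > 1.405	damaging	2	1
default_pfam_disorder	pfam_fraction_affected > 0; in_disorder == TRUE	damaging	2	1
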