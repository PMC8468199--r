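# Default pharmacophore feature-perception rules (SMARTS subset).
# centroid_rule: atom = first matched atom; ring-centroid = aromatic ring
# centroid; group-centroid = centroid of each contiguous matched-atom group
# of >= min_group atoms. tolerance (Angstrom) falls back to the per-kind
# default when empty (1.6; HYP 1.7). Identical to default_feature_rules().
pattern	kind	centroid_rule	min_group	tolerance
[#8]-[#1]	HBD	atom	1	NA
[#7]-[#1]	HBD	atom	1	NA
[#16]-[#1]	HBD	atom	1	NA
[#8]	HBA	atom	1	NA
[#7;H0;!X4;!$([#7]-[#6]=[#8]);!$([#7]-c)]	HBA	atom	1	NA
[C;!$([#6]~[#7,#8,#15,#16])]	HYP	group-centroid	3	NA
[F,Cl,Br,I]c	HYP	atom	1	NA
[a]	RA	ring-centroid	1	NA
[#7;+]	PI	atom	1	NA
[N;X3;!$([#7]-[#6]=[#8]);!$([#7]-c);!$([#7]~[#6]~[#7])]	PI	atom	1	NA
[#6](=[#7])-[#7]	PI	group-centroid	1	NA
[#6](=[#8])-[#8;H1,-]	NI	group-centroid	1	NA
[#15](=[#8])-[#8]	NI	group-centroid	1	NA
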