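# Codon:anticodon pairing selective constraints s (dimensionless, in [0,1]).
# Classes are named anticodon-position-34 base : codon-position-3 base.
# watson_crick covers all four canonical pairs; the wobble classes follow the
# standard prokaryotic tAI scheme (G34 reads U3; A34, read as inosine, reads
# C3 and weakly A3; U34 reads G3; lysidine-modified C34 reads A3 of AUA).
pairing_class	s
watson_crick	0
wobble_GU	0.41
wobble_IC	0.28
wobble_IA	0.9999
wobble_UG	0.68
lysidine_CA	0.89
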