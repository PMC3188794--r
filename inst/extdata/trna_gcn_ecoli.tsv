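# Approximate E. coli K-12 tRNA gene copy numbers by anticodon (RNA alphabet).
# Compiled from standard anticodon repertoires; initiator fMet genes excluded.
# The lysidine-modified Ile2 tRNA (reads AUA only) is listed under its genomic
# anticodon CAU together with the elongator Met tRNAs; the weight engine pairs
# it with codon AUA through the dedicated 'lysidine_CA' class.
# This is a bundled repository default, not data shipped with any publication;
# replace with organism-specific counts for production analyses.
anticodon	copy_number	amino_acid
GGC	2	Ala
UGC	3	Ala
ACG	4	Arg
CCG	1	Arg
UCU	1	Arg
CCU	1	Arg
GUU	4	Asn
GUC	3	Asp
GCA	1	Cys
UUG	2	Gln
CUG	2	Gln
UUC	4	Glu
GCC	4	Gly
UCC	1	Gly
CCC	1	Gly
GUG	1	His
GAU	3	Ile
CAU	3	Met/Ile2
UAA	1	Leu
CAA	1	Leu
UAG	1	Leu
CAG	4	Leu
GAG	1	Leu
UUU	6	Lys
GAA	2	Phe
GGG	1	Pro
UGG	1	Pro
CGG	1	Pro
GCU	1	Ser
GGA	2	Ser
UGA	1	Ser
CGA	1	Ser
GGU	2	Thr
UGU	1	Thr
CGU	1	Thr
CCA	1	Trp
GUA	3	Tyr
GAC	2	Val
UAC	5	Val
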