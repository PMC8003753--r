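# lantiscan sequence-signature models (synthetic, authored for this package)
#
# One model per line, tab-separated:
#   name <TAB> min_matches <TAB> patterns (';'-separated, PROSITE-style)
#   <TAB> description
# Pattern syntax: positions separated by '-'; 'x' = any residue;
# '[ABC]' = alternatives; '(n)' = repeat the preceding element n times.
#
# These degenerate patterns play the role of the Pfam domains used for
# locus typing (FtsX-like permease PF02687, S41 peptidase PF03572, histidine
# kinase, response regulator receiver, ABC nucleotide-binding domain). They
# are authored against this package's bundled synthetic exemplar proteins,
# not extracted from Pfam HMMs, and are validated on those exemplars.
FtsX_permease	1	L-D-[ILV]-F-[ST]-x-Q-[ILV]	FtsX-like membrane permease signature (BceB/NsrP-style subunits)
S41_peptidase	2	T-x-S-S-[AG]-E-[AM];G-Q-[ST]-D-x-N-P-W	S41 C-terminal processing peptidase: TASSAEM-like catalytic box plus N-domain anchor
HisKinase	2	[AG]-H-E-[ILV]-[KR]-[TN]-P-[ILV];G-[ST]-G-L-G-L-[AG]-[ILV]	Histidine kinase H-box and HATPase G-box
ResponseRegulator	2	[ILV](3)-D-D-[QE];G-[ILV]-S-[KR]-P-[FL]	Receiver-domain acidic pocket and switch signatures
ABC_NBD	2	[AG]-x(4)-G-K-[ST];[ILV](4)-D-[ED]	ABC transporter nucleotide-binding domain: Walker A and Walker B boxes
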