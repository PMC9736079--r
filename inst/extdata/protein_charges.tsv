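residue	atom	charge
ALL	N	-0.4157
ALL	H	0.2719
ALL	HN	0.2719
ALL	CA	0.0337
ALL	HA	0.0823
ALL	C	0.5973
ALL	O	-0.5679
ALL	OXT	-0.8055
GLY	CA	-0.0252
GLY	HA2	0.0698
GLY	HA3	0.0698
ALA	CB	-0.1825
ALA	HB1	0.0603
ALA	HB2	0.0603
ALA	HB3	0.0603
SER	CB	0.2117
SER	HB2	0.0352
SER	HB3	0.0352
SER	OG	-0.6546
SER	HG	0.4275
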