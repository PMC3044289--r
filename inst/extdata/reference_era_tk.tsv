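target	residue	resname	resno	type	w	ratio
ERA	R394	ARG	394	H	0.80	1.0
ERA	E353	GLU	353	H	0.64	0.8
ERA	H524	HIS	524	H	1.00	1.0
ERA	L387	LEU	387	V	1.00	0.9
ERA	L387	LEU	387	H	0.52	0.2
ERA	F404	PHE	404	V	0.90	1.0
ERA	V346	VAL	346	V	0.98	0.5
ERA	L391	LEU	391	V	0.61	0.9
ERA	L384	LEU	384	V	0.57	0.9
ERA	L525	LEU	525	H	0.53	0.9
TK	R222	ARG	222	H	1.00	0.8
TK	R222	ARG	222	E	1.00	0.0
TK	R222	ARG	222	V	0.62	0.4
TK	R163	ARG	163	H	0.99	0.6
TK	R163	ARG	163	E	0.40	0.0
TK	R163	ARG	163	V	0.56	0.8
TK	E83	GLU	83	V	0.54	0.2
TK	Y101	TYR	101	H	0.40	0.2
TK	Y101	TYR	101	V	0.45	0.0
TK	Q125	GLN	125	H	0.40	1.0
TK	Y172	TYR	172	V	1.00	1.0
TK	M128	MET	128	V	0.58	1.0
TK	W88	TRP	88	V	0.87	0.9
TK	H58	HIS	58	V	0.68	0.9
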