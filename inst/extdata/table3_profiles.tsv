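substrate	protein_id	sdp1	sdp2	sdp3	sdp4	sdp5	sdp6	sdp7	sdp8	sdp9
NH3	RcTIP2;2	T	K	T	V	A	S	A	P	S
NH3	RcNIP1;1	F	K	F	T	A	D	L	E	T
boric acid	RcPIP1;1	T	I	H	P	E	L	L	T	P
boric acid	RcPIP1;2	T	I	H	P	E	L	L	T	P
boric acid	RcPIP1;3	T	I	H	P	E	L	L	T	P
boric acid	RcPIP1;4	T	I	H	P	E	L	L	T	P
boric acid	RcPIP1;5	T	I	H	P	E	L	L	T	P
boric acid	RcNIP5;1	T	I	H	P	E	L	L	A	P
CO2	RcPIP1;1	V	M	C	A	I	D	W	D	W
CO2	RcPIP1;3	L	M	C	A	I	D	W	D	W
CO2	RcPIP1;4	L	M	C	A	I	D	W	D	W
CO2	RcPIP1;5	I	M	C	A	V	D	W	D	W
CO2	RcPIP2;2	I	M	C	A	V	D	W	D	W
CO2	RcPIP2;4	V	M	C	A	V	D	W	D	W
H2O2	RcPIP1;1	A	G	V	L	I	H	F	V	P
H2O2	RcPIP1;2	A	G	V	F	I	H	F	V	P
H2O2	RcPIP1;3	A	G	V	F	I	H	F	V	P
H2O2	RcPIP1;4	A	G	V	F	I	H	F	V	P
H2O2	RcPIP1;5	A	G	V	F	I	H	F	V	P
H2O2	RcPIP2;1	A	G	V	F	I	Q	F	V	P
H2O2	RcPIP2;2	A	G	V	F	I	Q	F	V	P
H2O2	RcPIP2;3	A	G	V	F	I	Q	F	V	P
H2O2	RcPIP2;4	A	G	V	F	I	H	F	V	P
H2O2	RcPIP2;5	A	G	V	F	I	H	F	V	P
H2O2	RcTIP5;1	S	A	L	A	I	Q	Y	V	P
H2O2	RcNIP2;1	A	A	L	L	V	I	Y	V	P
H2O2	RcNIP3;1	S	A	L	L	I	L	F	V	P
H2O2	RcNIP4;2	S	A	L	V	V	L	Y	V	P
H2O2	RcNIP5;1	S	A	L	V	V	L	Y	V	P
H2O2	RcXIP1;1	A	G	L	V	S	H	F	V	P
H2O2	RcXIP1;2	A	G	L	V	S	H	F	V	P
H2O2	RcXIP1;3	A	A	L	V	S	H	F	V	P
silicic acid	RcNIP2;1	S	F	V	H	G	N	R	T	Q
urea	RcPIP1;1	H	P	F	F	L	P	G	G	N
urea	RcPIP1;2	H	P	F	F	L	P	G	G	N
urea	RcPIP1;3	H	P	F	F	L	P	G	G	N
urea	RcPIP1;4	H	P	F	F	L	P	G	G	N
urea	RcPIP1;5	H	P	F	L	L	P	G	G	N
urea	RcPIP2;1	H	P	L	F	L	P	G	G	N
urea	RcPIP2;2	H	P	F	F	L	P	G	G	N
urea	RcPIP2;3	H	P	F	F	L	P	G	G	N
urea	RcPIP2;4	H	P	F	F	L	P	G	G	N
urea	RcPIP2;5	H	P	F	L	L	P	G	G	N
urea	RcTIP1;1	H	P	F	F	L	A	G	S	N
urea	RcTIP1;2	H	P	F	F	L	A	G	S	N
urea	RcTIP1;3	H	P	F	F	L	A	G	S	N
urea	RcTIP1;4	H	P	F	F	L	A	G	S	N
urea	RcTIP2;1	H	P	F	A	L	P	G	S	N
urea	RcTIP2;2	H	P	F	A	L	P	G	S	N
urea	RcTIP3;1	H	P	F	L	L	P	G	S	N
urea	RcTIP4;1	H	P	L	L	L	P	G	S	N
urea	RcTIP5;1	H	P	F	A	L	P	G	S	N
urea	RcNIP1;1	H	P	L	A	L	P	G	S	N
urea	RcNIP2;1	H	P	T	A	M	P	G	S	N
urea	RcNIP3;1	H	P	I	A	L	P	G	S	N
urea	RcNIP4;1	H	P	I	A	L	P	G	S	N
urea	RcNIP4;2	H	P	I	A	L	P	G	S	N
urea	RcNIP5;1	H	P	I	A	L	P	G	S	N
urea	RcNIP6;1	H	P	I	A	L	E	G	S	N
urea	RcNIP7;1	H	P	I	A	M	P	G	S	N
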