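name	index
SDP1	60
H2	90
SDP2	95
NPA_LB1	104
NPA_LB2	105
NPA_LB3	106
PHOS1	115
P1	130
SDP3	140
SDP4	150
SDP5	160
SDP6	185
H5	214
NPA_LE1	224
NPA_LE2	225
NPA_LE3	226
LE1	231
LE2	236
SDP7	240
P2	250
P3	254
SDP8	258
SDP9	262
P4	270
P5	271
PHOS2	274
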