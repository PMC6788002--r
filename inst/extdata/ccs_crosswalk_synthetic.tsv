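icd_prefix	ccs
E1	49
E110	50
E112	50
I1	98
I10	99
I21	100
I25	101
I50	108
I63	109
J06	126
J18	122
J44	127
K21	138
K29	139
K76	151
N17	157
N39	159
R73	259
R81	259
A09	135
B18	6
C34	19
D50	59
F32	203
G45	112
H25	86
L03	197
M17	202
M54	205
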