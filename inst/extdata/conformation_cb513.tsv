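aa	H	E	C
A	0.49	0.16	0.35
R	0.42	0.19	0.39
N	0.27	0.13	0.6
D	0.31	0.11	0.58
C	0.26	0.29	0.45
E	0.49	0.15	0.36
Q	0.46	0.16	0.38
G	0.16	0.14	0.7
H	0.3	0.22	0.48
I	0.35	0.37	0.28
L	0.45	0.24	0.31
K	0.4	0.17	0.43
M	0.44	0.23	0.33
F	0.35	0.3	0.35
P	0.18	0.09	0.74
S	0.28	0.19	0.54
T	0.25	0.27	0.48
W	0.37	0.29	0.35
Y	0.34	0.3	0.36
V	0.3	0.41	0.29
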