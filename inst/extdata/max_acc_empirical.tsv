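aa	max_acc
A	121
R	265
N	187
D	187
C	148
E	214
Q	214
G	97
H	216
I	195
L	191
K	230
M	203
F	228
P	154
S	143
T	163
W	264
Y	255
V	165
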