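element	mass
H	1.0078250319
C	12.0000000000
N	14.0030740052
O	15.9949146221
S	31.9720706900
P	30.9737615100
Na	22.9897692800
K	38.9637064900
Cl	34.9688527100
F	18.9984032000
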