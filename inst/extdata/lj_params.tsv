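element	epsilon_kj	rmin_half
H	0.1841	1.443
C	0.4393	1.9255
N	0.2887	1.830
O	0.2510	1.750
F	0.2092	1.682
P	1.2761	2.0735
S	1.1464	2.0175
Cl	0.9497	1.9735
Br	1.0502	2.0945
I	1.4184	2.250
Na	0.1255	1.4915
K	0.1464	1.906
Mg	0.4644	1.5105
Ca	0.9958	1.6995
Mn	0.0544	1.4405
Fe	0.0544	1.456
Co	0.0586	1.436
Ni	0.0628	1.417
Cu	0.0209	1.7435
Zn	0.5188	1.3815
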