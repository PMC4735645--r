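label	x	y	z
Fp1	-21.2	66.9	12.1
Fp2	24.3	66.3	12.5
F7	-52.1	28.6	3.8
F3	-39.7	25.3	44.7
Fz	0.0	26.8	60.6
F4	41.9	27.5	43.9
F8	52.7	28.7	3.1
T7	-65.7	-17.6	-2.8
C3	-53.2	-16.4	57.8
Cz	0.4	-9.2	66.9
C4	54.6	-16.3	57.5
T8	67.4	-18.5	-3.4
P7	-54.9	-63.5	-2.0
P3	-39.5	-76.3	47.4
Pz	0.3	-62.1	64.5
P4	36.8	-74.9	49.2
P8	55.7	-64.6	-3.6
O1	-26.8	-100.2	8.8
O2	24.1	-100.5	8.8
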