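label	x	y	z
BA1_L	-48	-24	50
BA1_R	48	-24	50
BA2_L	-44	-30	48
BA2_R	44	-30	48
BA3_L	-40	-24	52
BA3_R	40	-24	52
BA4_L	-38	-20	52
BA4_R	38	-20	52
BA5_L	-16	-44	60
BA5_R	16	-44	60
BA6_L	-28	-2	52
BA6_R	28	-2	52
BA7_L	-18	-62	54
BA7_R	18	-62	54
BA8_L	-24	24	46
BA8_R	24	24	46
BA9_L	-30	36	32
BA9_R	30	36	32
BA10_L	-26	54	8
BA10_R	26	54	8
BA11_L	-22	38	-16
BA11_R	22	38	-16
BA13_L	-38	0	4
BA13_R	38	0	4
BA17_L	-12	-86	2
BA17_R	12	-86	2
BA18_L	-20	-88	6
BA18_R	20	-88	6
BA19_L	-32	-80	14
BA19_R	32	-80	14
BA20_L	-48	-26	-24
BA20_R	48	-26	-24
BA21_L	-56	-26	-10
BA21_R	56	-26	-10
BA22_L	-56	-26	4
BA22_R	56	-26	4
BA23_L	-6	-50	26
BA23_R	6	-50	26
BA24_L	-6	8	34
BA24_R	6	8	34
BA25_L	-6	16	-10
BA25_R	6	16	-10
BA27_L	-16	-34	-4
BA27_R	16	-34	-4
BA28_L	-22	-14	-26
BA28_R	22	-14	-26
BA29_L	-8	-46	10
BA29_R	8	-46	10
BA30_L	-14	-54	10
BA30_R	14	-54	10
BA31_L	-10	-54	32
BA31_R	10	-54	32
BA32_L	-8	24	30
BA32_R	8	24	30
BA33_L	-4	12	22
BA33_R	4	12	22
BA34_L	-20	0	-16
BA34_R	20	0	-16
BA35_L	-24	-26	-20
BA35_R	24	-26	-20
BA36_L	-30	-30	-18
BA36_R	30	-30	-18
BA37_L	-48	-56	-12
BA37_R	48	-56	-12
BA38_L	-40	14	-28
BA38_R	40	14	-28
BA39_L	-46	-62	30
BA39_R	46	-62	30
BA40_L	-52	-42	38
BA40_R	52	-42	38
BA41_L	-46	-26	10
BA41_R	46	-26	10
BA42_L	-60	-24	10
BA42_R	60	-24	10
BA43_L	-58	-12	18
BA43_R	58	-12	18
BA44_L	-50	12	14
BA44_R	50	12	14
BA45_L	-50	26	8
BA45_R	50	26	8
BA46_L	-44	38	16
BA46_R	44	38	16
BA47_L	-42	28	-12
BA47_R	42	28	-12
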