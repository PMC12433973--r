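control_bin	[-1,-0.75]	(-0.75,-0.5]	(-0.5,-0.25]	(-0.25,0]	(0,0.25]	(0.25,0.5]	(0.5,0.75]	(0.75,1]
[-1,-0.75]	41	339	49	2	0	0	0	0
(-0.75,-0.5]	179	7912	8096	1531	198	13	0	0
(-0.5,-0.25]	95	8497	28130	22011	7256	991	51	1
(-0.25,0]	4	3070	34302	86217	66512	13967	1055	15
(0,0.25]	0	595	12630	63063	80636	32892	4540	59
(0.25,0.5]	0	15	1282	8436	20658	23494	9995	382
(0.5,0.75]	0	0	85	328	1555	7127	9263	791
(0.75,1]	0	0	1	6	8	109	893	269
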