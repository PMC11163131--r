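drug	M1	M2	mM2	H	F	HM	SD	FRR	SRR
Naphazoline	84	98	3.55	7.88	204	400	37.33	4.074	11.198
Tetrahydrozoline	80	95	3.33	7.4	196	521	35	3.355	7.449
Oxymetazoline	100	117	4.02	8.21	280	514	51.83	3.690	18.005
Pheniramine	86	96	4.13	8.56	206	398	41.66	4.433	13.529
Antazoline	100	113	4.52	9.83	236	462	45.66	5.067	13.776
Emedastine	112	131	5.02	10.6	276	538	51.33	5.490	16.328
Vidarabine	104	128	4.19	8.8	276	532	47.66	4.650	16.159
Foscarnet	30	30	1.5	2.48	96	156	21.50	1.407	10.041
Ciprofloxacin	128	155	5.02	10.83	336	646	59	5.740	19.926
Moxifloxacin	166	207	6.22	13.53	444	858	74	6.464	24.623
Gatifloxacin	150	185	5.86	12.4	402	772	69	6.590	23.889
Ofloxacin	146	180	5.52	11.83	394	754	67.66	6.326	23.390
Tobramycin	168	202	7.11	14.26	452	856	80	7.602	31.449
Amoxicillin	136	161	5.55	11.05	384	706	71.66	5.990	27.267
Dexamethasone	168	221	5.81	12.08	518	960	79.83	6.386	29.544
Chloramphenicol	94	106	4.61	8.8	244	456	49.66	4.655	19.855
Besifloxacin	150	184	5.77	12.33	402	770	69.66	6.576	23.890
Cyclopentolate	104	119	4.72	9.61	272	510	52	5.053	18.327
Nepafenac	94	108	4.27	8.73	238	454	46.33	4.586	16.160
Azithromycin	274	327	11.23	22.10	786	1440	142.25	11.985	52.669
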