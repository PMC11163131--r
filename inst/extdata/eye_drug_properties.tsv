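drug	MW	MW_unc	BP	BP_unc	EV	EV_unc	FP	FP_unc	MR	MR_unc	MV	MV_unc
Naphazoline	210.274	0	440.5	24	67.1	3	220.2	22.9	65.5	0.5	181.8	0
Tetrahydrozoline	200.279	0	393.5	21	61.8	3	191.8	22.1	60.9	0.5	165.7	0
Oxymetazoline	260.375	0	431.9	33	71.4	3	215.0	25.4	77.8	0.5	240.9	0
Pheniramine	240.343	0	348.3	37	59.3	3	164.5	26.5	75.9	0.3	236.1	0
Antazoline	265.353	0	475.5	38	73.9	3	241.4	26.8	83.3	0.5	241.0	0
Emedastine	302.414	0	446.6	55	70.5	3	223.9	31.5	89.2	0.5	262.6	0
Vidarabine	267.241	0	676.3	65	104.3	3	362.8	34.3	60.0	0.5	128.2	0
Foscarnet	126.005	0	490.7	28	82.9	6	250.6	24.0	18.2	0.3	58.8	0
Ciprofloxacin	331.341	0	581.8	50	91.5	3	305.6	30.1	83.3	0.3	226.8	0
Moxifloxacin	401.431	0	636.4	55	98.8	3	338.7	31.5	101.8	0.3	285.0	0
Gatifloxacin	375.394	0	607.8	55	95.0	3	321.4	31.5	94.6	0.3	270.8	0
Ofloxacin	361.367	0	571.5	50	90.1	3	299.4	30.1	91.1	0.4	244.0	0
Tobramycin	467.514	0	775.4	60	128.7	6	422.8	32.9	111.7	0.4	305.9	0
Amoxicillin	365.404	0	743.2	60	113.7	3	403.3	32.9	91.5	0.4	236.2	0
Dexamethasone	392.461	0	568.2	50	98	6	297.5	30.1	100.2	0.4	296.2	0
Chloramphenicol	323.129	0	644.9	55	100	3	343.8	31.5	72.6	0.3	208.8	0
Besifloxacin	393.840	0	607.0	55	94.9	3	320.9	31.5	97.6	0.3	268.0	0
Cyclopentolate	291.385	0	409.6	20	69.8	3	201.5	21.8	82.4	0.3	256.5	0
Nepafenac	254.284	0	562.5	50	84.6	3	294.0	30.1	73.4	0.3	203.4	0
Azithromycin	748.984	0	822.1	65	136	6.0	451.0	34.3	197.6	0.4	632.7	0
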