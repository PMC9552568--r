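state	period	source	confirmed	probable	published_total	published_pct
California	2004-2018	Newborn screening	1612	12	1624	16.4
California	2004-2018	Clinic sites	2592	147	2739	27.8
California	2004-2018	Medicaid and CHIP	2058	4441	6499	65.8
California	2004-2018	Hospital discharge	1812	5206	7018	71.1
California	2004-2018	Deduplicated total	3389	6486	9875	100.0
California	2018	Newborn screening	1014	2	1016	16.9
California	2018	Clinic sites	1734	59	1793	29.8
California	2018	Medicaid and CHIP	1795	3325	5120	84.9
California	2018	Hospital discharge	1502	3189	4691	77.8
California	2018	Deduplicated total	2119	3908	6027	100.0
Georgia	2004-2018	Newborn screening	2359	128	2487	16.8
Georgia	2004-2018	Clinic sites	8150	129	8279	56.0
Georgia	2004-2018	Medicaid and CHIP	6184	3319	9503	64.3
Georgia	2004-2018	State health benefit plan	249	191	440	3.0
Georgia	2004-2018	Hospital discharge	7324	5473	12797	86.6
Georgia	2004-2018	Deduplicated total	8403	6374	14777	100.0
Georgia	2018	Newborn screening	1882	43	1925	21.1
Georgia	2018	Clinic sites	5743	67	5810	63.6
Georgia	2018	Medicaid and CHIP	4653	2009	6662	73.0
Georgia	2018	Hospital discharge	5427	2918	8345	91.3
Georgia	2018	Deduplicated total	5856	3285	9141	100.0
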