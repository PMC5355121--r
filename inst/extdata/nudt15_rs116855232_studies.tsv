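study_id	author	year	ethnicity	disease	endpoints	tt_case	ct_case	cc_case	tt_ctrl	ct_ctrl	cc_ctrl	dose_tt_n	dose_tt_mean	dose_tt_sd	dose_tt_norm_mean	dose_tt_norm_sd	dose_ct_n	dose_ct_mean	dose_ct_sd	dose_ct_norm_mean	dose_ct_norm_sd	dose_cc_n	dose_cc_mean	dose_cc_sd	dose_cc_norm_mean	dose_cc_norm_sd	dose_tcar_n	dose_tcar_mean	dose_tcar_sd	dose_tcar_norm_mean	dose_tcar_norm_sd
Yang-2014	Suk-Kyun Yang	2014	Korean	IBD	myelotoxicity,dose	14	133	199	0	43	589	14	2.335	0.485	0.522	0.108	176	3.697	2.145	0.827	0.48	788	4.472	2.436	1	0.545					
Kakuta-2015	Y Kakuta	2015	Japanese	IBD	myelotoxicity,dose	5	10	19	0	13	88						23	1.613	0.891	0.557	0.307	107	2.915	1.203	1	0.413					
Asada-2016	Ayumi Asada	2016	Japanese	IBD	myelotoxicity,dose	2	18	25	0	14	102	2	2.12		0.872		32	2.26	1.13	0.93	0.465	127	2.43	1.27	1	0.523					
Zhu-2016	X Zhu	2016	Chinese Han	IBD	myelotoxicity	4	36	25	0	17	171																				
Shah-2016	Swarup A V Shah	2016	Indian	IBD	dose	1	5	0	0	3	60											60	2.858	0.566	1	0.198	9	2.066	0.566	0.723	0.198
YangJJ-2015-EastAsian	Jun J Yang	2015	East Asian	ALL	dose	1	10	50				1	10.125		0.169		10	35.55	11.25	0.594	0.188	50	59.85	17.85	1	0.298					
YangJJ-2015-Hispanic	Jun J Yang	2015	Hispanic	ALL	dose	1	16	205				1	2.175		0.033		16	52.425	13.4	0.796	0.355	205	65.85	16.65	1	0.253					
YangJJ-2015-Other	Jun J Yang	2015	Other	ALL	dose	0	5	375									5	59.475	13.95	0.924	0.217	375	64.35	17.55	1	0.273					
Tanaka-2015	Yoichi Tanaka	2015	Japanese	ALL	myelotoxicity	5	13	20	1	5	48																				
Liang-2015	D-C Liang	2015	Taiwan Chinese	ALL	dose	2	70	238				2	18.8	7.4	0.213	0.084	70	61.4	23.4	0.696	0.265	238	88.2	30.6	1	0.347					
Chiengthong-2016	Kanhatai Chiengthong	2016	Thai	ALL	myelotoxicity,dose	1	9	18	1	1	52											70	86.542	9.525	1	0.11	12	54.608	8.719	0.631	0.101
Moriyama-2016-Guatemala	Takaya Moriyama	2016	Guatemala	ALL	dose	1	18	162				1	8.944		0.128		18	54.954	34.516	0.789	0.496	162	69.638	30.261	1	0.435					
Moriyama-2016-Singapore	Takaya Moriyama	2016	Singaporean	ALL	dose	1	17	65				1	5.522		0.06		17	65.894	25.765	0.721	0.282	65	91.354	27.674	1	0.303					
Moriyama-2016-Japan	Takaya Moriyama	2016	Japanese	ALL	dose	1	9	22				1	5.013		0.05		9	69.95	28.912	0.702	0.29	22	99.674	34.231	1	0.343					
Suzuki-2016	Hisato Suzuki	2016	Japanese	ALL	myelotoxicity,dose	0	10	36	0	0	5						10	59.946	16.405	0.913	0.25	41	65.647	23.887	1	0.364					
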