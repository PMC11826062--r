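site_id	location	source	fluid_type	ph	temperature_c	si_molal	pct_serp_printed	h2_molal	dic_molal	acetate_molal	formate_molal
140115Z	Al Banah	surface	type2	11.3	32.2	1.4E-06	100.0	2.3E-04	3.4E-05	3.2E-06	3.0E-06
140115X	Al Banah	surface	type2	11.4	29.5	2.2E-06	99.9	2.3E-04	3.1E-05	4.1E-06	4.3E-06
140115Y	Al Banah	surface	type2	11.6	24.5	2.2E-06	99.9	2.1E-05	1.1E-04	2.9E-06	1.7E-06
140114S	Falej North	surface	mixed	7.7	21	2.0E-04	76.5	1.5E-08	4.4E-03	8.5E-07
140114U	Falej North	surface	type2	11.4	21.7	7.4E-06	99.3	1.7E-08	1.8E-04	2.5E-06	3.3E-06
140114V	Falej North	surface	type2	11.4	24.4	2.8E-06	99.8	1.7E-07	2.3E-04		9.8E-07
140114T	Falej North	surface	type2	11.4	27.2	1.8E-06	99.9	2.8E-05	4.2E-05	3.0E-06	5.5E-06
140114R	Falej North	surface	type2	11.6	21.1	2.4E-06	99.9	1.2E-08	4.2E-05
140113O	Falej South	surface	type2	11.4	28.4	3.7E-06	99.7	3.9E-05	5.7E-05	3.9E-06	4.8E-06
140113P	Falej South	surface	type2	11.5	25.9	1.9E-06	99.9	6.6E-05	4.6E-05	2.2E-06	1.6E-06
140111G	Qafifah	surface	mixed	8.9	22.6	2.8E-04	67.5	2.4E-07	4.1E-03	1.2E-06
140111H	Qafifah	surface	mixed	10.2	20.2	1.5E-04	83.0	1.1E-06	1.8E-03	6.6E-07	2.0E-06
140111I	Qafifah	surface	mixed	10.9	18.8	1.0E-04	88.3	2.1E-06	8.5E-04	9.2E-07	1.3E-06
140111F	Qafifah	surface	type2	11.6	23.8	1.1E-05	98.9	2.6E-04	4.1E-05	1.8E-06	1.9E-06
140116B	Shmait	surface	mixed	7.9	26.5	3.0E-04	64.4	6.2E-08	5.1E-03	1.5E-06
140116C	Shmait	surface	mixed	8.7	27.3	2.8E-04	67.2	2.2E-06	4.7E-03	1.6E-06
140116D	Shmait	surface	mixed	9.1	27.1	2.6E-04	69.4	1.3E-05	4.0E-03	1.4E-06
140117J	Shmait	surface	mixed	11.3	31.6	4.9E-05	94.4	2.2E-04	7.0E-05		5.3E-07
140117I	Shmait	surface	type2	11.3	32.3	2.0E-06	99.9	2.3E-04	4.7E-05		4.9E-07
140117G	Shmait	surface	type2	11.4	30.5	1.5E-06	100.0	2.8E-06	1.9E-05		1.5E-06
140117F	Shmait	surface	type2	11.5	26.2	2.7E-06	99.8	2.7E-04	2.9E-05	1.5E-06	1.2E-06
140117H	Shmait	surface	type2	11.5	29.6	1.7E-06	99.9	2.3E-04	2.9E-05		1.1E-06
140110B	Wadi Dima	surface	mixed	8.4	23.5	1.8E-04	78.5	7.0E-09	3.6E-03		4.4E-07
140112L	Wadi Dima	surface	mixed	9.8	21.3	1.1E-04	87.0	9.0E-09	1.9E-03		7.4E-07
140110D	Wadi Dima	surface	mixed	10.4	21.8	9.1E-05	89.3	5.6E-08	8.1E-04		7.5E-07
140112M	Wadi Dima	surface	type2	11.4	28.2	5.6E-06	99.5	3.1E-05	5.2E-05		7.4E-07
140112K	Wadi Dima	surface	type2	11.4	26.9	3.9E-06	99.7	4.9E-07	3.6E-05	7.9E-07	9.4E-07
140110C	Wadi Dima	surface	type2	11.4	27	4.3E-06	99.6	6.4E-06	5.3E-05	1.3E-06	4.2E-06
NSHQ142014	Well	well	type2	11.4	34.9	7.0E-06	99.3	6.7E-04
NSHQ142015	Well	well	type2	11.3	35.3	5.0E-06	99.6	2.9E-03	1.9E-04	1.2E-06	1.7E-06
NSHQ142016	Well	well	type2	11.2	35.8	5.0E-06	99.6	2.2E-04
NSHQ212015	Well	well	mixed	7.4	33.7	7.8E-04	7.8		2.6E-03	4.9E-07	1.1E-06
NSHQ3B2015	Well	well	mixed	8.4	30.1	2.5E-04	71.0		2.5E-03	4.7E-07	1.2E-06
NSHQ42014	Well	well	mixed	10.6	35.1	2.0E-04	76.8		2.2E-04	4.4E-06	1.5E-06
NSHQ42015	Well	well	mixed	10.5	33.3	1.5E-05	98.4		1.8E-04	1.4E-06	2.3E-06
WAB1032015	Well	well	mixed	8.2	30.4	4.8E-04	43.5		2.3E-03	4.3E-07	1.1E-06
WAB1032016	Well	well	type1	8.2	33.8	8.5E-04	0.0
WAB1042016	Well	well	mixed	8.5	33.4	2.1E-04	75.3
WAB1052016	Well	well	mixed	8.3	31.6	4.3E-05	95.1
WAB1882015	Well	well	mixed	8.7	34.2	2.3E-04	72.7		2.3E-03	3.8E-06	1.0E-06
WAB1882016	Well	well	mixed	7.6	33	7.9E-04	7.4
WAB552015	Well	well	type2	9.3	30	6.0E-06	99.4		2.6E-03	2.0E-06	1.4E-06
WAB552016	Well	well	type2	9.2	34.7	6.0E-06	99.4
WAB562015	Well	well	type2	10.6	33.3	1.0E-05	99.0	1.8E-04
WAB712015	Well	well	mixed	11.0	33.1	1.7E-05	98.1			6.3E-07	1.5E-06
WAB712016	Well	well	mixed	11.1	34.5	2.4E-05	97.3
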