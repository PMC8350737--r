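reaction_id	dg0_prime_kj_mol	kcat_s	km_entries	mw_g_mol
glf	0	100	glc_ext:40.21;xyl_ext:80.96	50000
glk	-17	150	glc:0.6;atp:0.8;g6p:12;adp:0.7	33000
g6pdh	1.5	200	g6p:0.11;nadp:0.02;pgl6:0.5;nadph:0.017	55000
pgl	-20	300	pgl6:0.08;pg6:2	27000
edd	-42	120	pg6:0.1;kdpg:1	63000
eda	14	100	kdpg:0.3;pyr:10;g3p:1	24000
gapdh	20	80	g3p:0.6;nad:0.09;pi:1.5;dpg13:0.01;nadh:0.01	37000
pgk	-19	250	dpg13:0.03;adp:0.25;pg3:1.2;atp:0.4	42000
pgm	4.4	170	pg3:0.45;pg2:0.12	28000
eno	-4	160	pg2:0.05;pep:0.3	46000
pyk	-27	220	pep:0.3;adp:0.3;pyr:10;atp:1	51000
als	-25	60	pyr:8	230000
aldc	-20	110	alac:2.5	29000
bdh	-22	90	actn:1.2;nadh:0.04;bdo:30;nad:0.3	38000
xyl	4	30	xyl:5;xlu:12	49000
xk	-24	130	xlu:0.3;atp:0.6;x5p:2;adp:0.5	52000
rpe	3.4	200	x5p:0.9;ru5p:1.5	25000
rpi	-2	250	ru5p:0.8;r5p:2.3	23000
tkt1	-3.8	70	x5p:0.3;r5p:0.4;s7p:4;g3p:2.1	72000
tal	-0.7	90	s7p:0.18;g3p:2.2;f6p:1.2;e4p:0.09	35000
tkt2	-10	70	x5p:0.3;e4p:0.09;f6p:1.5;g3p:2.1	72000
pgi	-2.5	400	f6p:0.15;g6p:0.28	61000
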