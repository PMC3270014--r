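# Idealized heavy-atom geometry for the four standard deoxyribonucleotides
# (synthetic reference coordinates, one rigid conformer per residue; angstrom).
resname	atom	element	x	y	z
DA	P	P	0.9340	-0.1560	-4.6360
DA	OP1	O	1.7810	0.9960	-4.2550
DA	OP2	O	-0.2040	0.3310	-5.6650
DA	O5'	O	0.2410	-0.7710	-3.3200
DA	C5'	C	-0.5490	0.2700	-2.7440
DA	C4'	C	-1.2390	-0.2510	-1.4820
DA	O4'	O	-0.2670	-0.5640	-0.4580
DA	C3'	C	-2.1050	0.8590	-0.8350
DA	O3'	O	-3.4090	0.8950	-1.4180
DA	C2'	C	-2.1730	0.3980	0.6400
DA	C1'	C	-0.9650	-0.5450	0.7970
DA	N9	N	-0.0780	-0.0470	1.8520
DA	C8	C	0.9620	0.8170	1.6890
DA	N7	N	1.5350	1.0440	2.8350
DA	C5	C	0.8970	0.3460	3.8050
DA	C6	C	1.0690	0.1960	5.1910
DA	N6	N	2.0790	0.8690	5.8560
DA	N1	N	0.2360	-0.6030	5.8500
DA	C2	C	-0.7290	-1.2490	5.2240
DA	N3	N	-0.9250	-1.1440	3.9270
DA	C4	C	-0.1420	-0.3680	3.1840
DC	P	P	0.9870	-0.0170	-3.8940
DC	OP1	O	1.8020	1.0990	-3.3650
DC	OP2	O	-0.1190	0.5600	-4.9100
DC	O5'	O	0.2550	-0.7720	-2.6740
DC	C5'	C	-0.5710	0.1960	-2.0270
DC	C4'	C	-1.3000	-0.4590	-0.8520
DC	O4'	O	-0.3630	-0.8630	0.1710
DC	C3'	C	-2.2060	0.5690	-0.1290
DC	O3'	O	-3.4880	0.6490	-0.7560
DC	C2'	C	-2.3220	-0.0400	1.2880
DC	C1'	C	-1.1060	-0.9810	1.3950
DC	N1	N	-0.2670	-0.5840	2.5280
DC	C2	C	0.2700	0.6480	2.5630
DC	O2	O	0.0520	1.4240	1.6470
DC	N3	N	1.0370	1.0350	3.5810
DC	C4	C	1.2910	0.2120	4.5890
DC	N4	N	2.0850	0.6220	5.6350
DC	C5	C	0.7460	-1.0880	4.5800
DC	C6	C	-0.0350	-1.4650	3.5410
DG	P	P	-0.8180	-0.3210	4.9350
DG	OP1	O	-1.7740	0.7660	4.6300
DG	OP2	O	0.3120	0.2240	5.9410
DG	O5'	O	-0.1260	-0.8260	3.5720
DG	C5'	C	0.5500	0.3000	3.0110
DG	C4'	C	1.2330	-0.1130	1.7060
DG	O4'	O	0.2530	-0.4710	0.7050
DG	C3'	C	1.9760	1.0910	1.0730
DG	O3'	O	3.2940	1.2180	1.6120
DG	C2'	C	2.0260	0.6920	-0.4210
DG	C1'	C	0.8970	-0.3450	-0.5730
DG	N9	N	-0.0680	0.1110	-1.5750
DG	C8	C	-1.1720	0.8770	-1.3410
DG	N7	N	-1.8040	1.0940	-2.4580
DG	C5	C	-1.1450	0.4820	-3.4720
DG	C6	C	-1.3610	0.3770	-4.8660
DG	O6	O	-2.3210	0.9140	-5.3910
DG	N1	N	-0.4730	-0.3270	-5.6010
DG	C2	C	0.5930	-0.9280	-5.0030
DG	N2	N	1.4740	-1.6430	-5.7740
DG	N3	N	0.8040	-0.8390	-3.7090
DG	C4	C	-0.0270	-0.1520	-2.9170
DT	P	P	-3.9680	-1.6650	3.1180
DT	OP1	O	-4.4060	-2.5990	4.2080
DT	OP2	O	-4.9010	-0.3600	2.9200
DT	O5'	O	-2.4930	-1.0280	3.3150
DT	C5'	C	-2.0050	-0.1360	2.3270
DT	C4'	C	-0.6110	0.3280	2.7280
DT	O4'	O	0.2470	-0.8290	2.7640
DT	C3'	C	0.0080	1.2860	1.7200
DT	O3'	O	0.9650	2.1210	2.3680
DT	C2'	C	0.7100	0.3600	0.7540
DT	C1'	C	1.1570	-0.7780	1.6570
DT	N1	N	1.1640	-2.0470	0.9890
DT	C2	C	2.3330	-2.5440	0.3740
DT	O2	O	3.4100	-1.9450	0.3630
DT	N3	N	2.1940	-3.7930	-0.2400
DT	C4	C	1.0470	-4.5700	-0.3000
DT	O4	O	0.9950	-5.6630	-0.8570
DT	C5	C	-0.1430	-3.9800	0.3690
DT	C7	C	-1.4200	-4.7570	0.3470
DT	C6	C	-0.0130	-2.7840	0.9580
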