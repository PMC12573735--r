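symbol	number	mass_amu	vdw_radius_angstrom	source
H	1	1.0080	1.20	bondi1964
He	2	4.0030	1.40	bondi1964
Li	3	6.9410	1.82	bondi1964
Be	4	9.0120	1.53	mantina2009
B	5	10.8120	1.92	mantina2009
C	6	12.0110	1.70	bondi1964
N	7	14.0070	1.55	bondi1964
O	8	15.9990	1.52	bondi1964
F	9	18.9980	1.47	bondi1964
Ne	10	20.1800	1.54	bondi1964
Na	11	22.9900	2.27	bondi1964
Mg	12	24.3050	1.73	bondi1964
Al	13	26.9820	1.84	mantina2009
Si	14	28.0860	2.10	bondi1964
P	15	30.9740	1.80	bondi1964
S	16	32.0670	1.80	bondi1964
Cl	17	35.4530	1.75	bondi1964
Ar	18	39.9480	1.88	bondi1964
K	19	39.0980	2.75	bondi1964
Ca	20	40.0780	2.31	mantina2009
Sc	21	44.9560	2.30	rdkit2024
Ti	22	47.8670	2.15	rdkit2024
V	23	50.9440	2.05	rdkit2024
Cr	24	51.9960	2.05	rdkit2024
Mn	25	54.9380	2.05	rdkit2024
Fe	26	55.8450	2.05	rdkit2024
Co	27	58.9330	2.00	rdkit2024
Ni	28	58.6930	1.63	bondi1964
Cu	29	63.5460	1.40	bondi1964
Zn	30	65.3900	1.39	bondi1964
Ga	31	69.7230	1.87	bondi1964
Ge	32	72.6100	2.11	mantina2009
As	33	74.9220	1.85	bondi1964
Se	34	78.9600	1.90	bondi1964
Br	35	79.9040	1.85	bondi1964
Kr	36	83.8000	2.02	bondi1964
Rb	37	85.4680	3.03	mantina2009
Sr	38	87.6200	2.49	mantina2009
Y	39	88.9060	2.40	rdkit2024
Zr	40	91.2240	2.30	rdkit2024
Nb	41	92.9060	2.15	rdkit2024
Mo	42	95.9400	2.10	rdkit2024
Tc	43	98.0000	2.05	rdkit2024
Ru	44	101.0700	2.05	rdkit2024
Rh	45	102.9060	2.00	rdkit2024
Pd	46	106.4200	1.63	bondi1964
Ag	47	107.8680	1.72	bondi1964
Cd	48	112.4120	1.58	bondi1964
In	49	114.8180	1.93	bondi1964
Sn	50	118.7110	2.17	bondi1964
Sb	51	121.7600	2.06	mantina2009
Te	52	127.6000	2.06	bondi1964
I	53	126.9040	1.98	bondi1964
Xe	54	131.2900	2.16	bondi1964
Cs	55	132.9050	3.43	mantina2009
Ba	56	137.3280	2.68	mantina2009
La	57	138.9060	2.50	rdkit2024
Ce	58	140.1160	2.48	rdkit2024
Pr	59	140.9080	2.47	rdkit2024
Nd	60	144.2400	2.45	rdkit2024
Pm	61	145.0000	2.43	rdkit2024
Sm	62	150.3600	2.42	rdkit2024
Eu	63	151.9640	2.40	rdkit2024
Gd	64	157.2500	2.38	rdkit2024
Tb	65	158.9250	2.37	rdkit2024
Dy	66	162.5000	2.35	rdkit2024
Ho	67	164.9300	2.33	rdkit2024
Er	68	167.2600	2.32	rdkit2024
Tm	69	168.9340	2.30	rdkit2024
Yb	70	173.0400	2.28	rdkit2024
Lu	71	174.9670	2.27	rdkit2024
Hf	72	178.4900	2.25	rdkit2024
Ta	73	180.9480	2.20	rdkit2024
W	74	183.8400	2.10	rdkit2024
Re	75	186.2070	2.05	rdkit2024
Os	76	190.2300	2.00	rdkit2024
Ir	77	192.2170	2.00	rdkit2024
Pt	78	195.0780	1.75	bondi1964
Au	79	196.9670	1.66	bondi1964
Hg	80	200.5900	1.55	bondi1964
Tl	81	204.3830	1.96	bondi1964
Pb	82	207.2000	2.02	bondi1964
Bi	83	208.9800	2.07	mantina2009
Po	84	209.0000	1.97	mantina2009
At	85	210.0000	2.02	mantina2009
Rn	86	222.0000	2.20	mantina2009
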