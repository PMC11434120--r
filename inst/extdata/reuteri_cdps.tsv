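no	display_name	printed_formula	observed_mz	rt	isomer_printed	novel
1	cyclo(Gly-Pro)	C7H10N2O2	155.0817	3.62	FALSE	FALSE
2	cyclo(Ala-Pro)	C8H12N2O2	169.0971	5.05	FALSE	FALSE
3	cyclo(Ala-Val)	C8H14N2O2	171.1127	7.57	TRUE	FALSE
4	cyclo(Ala-Val)	C8H14N2O2	171.1132	9.68	TRUE	FALSE
5	cyclo(Ser-Pro)	C8H12N2O3	185.0918	1.20	TRUE	FALSE
6	cyclo(Ser-Pro)	C8H12N2O3	185.0921	2.85	TRUE	FALSE
7	cyclo(Ala-Hyp)	C8H12N2O3	185.0921	2.20	TRUE	FALSE
8	cyclo(Ala-Hyp)	C8H12N2O3	185.0921	2.52	TRUE	FALSE
9	cyclo(Ala-Leu)	C9H16N2O2	185.1281	13.34	FALSE	FALSE
10	cyclo(Ala-Ile)	C9H16N2O2	185.1283	12.02	FALSE	FALSE
11	cyclo(Pro-Pro)	C10H14N2O2	195.1181	10.03	FALSE	FALSE
12	cyclo(Val-Pro)	C10H16N2O2	197.1286	12.71	TRUE	FALSE
13	cyclo(Val-Pro)	C10H16N2O2	197.1286	13.11	TRUE	FALSE
14	cyclo(Thr-Pro)	C9H14N2O3	199.1073	3.15	TRUE	FALSE
15	cyclo(Thr-Pro)	C9H14N2O3	199.1078	4.21	TRUE	FALSE
16	cyclo(Val-Val)	C10H18N2O2	199.1436	18.61	FALSE	FALSE
17	cyclo(Ser-Leu)	C9H16N2O3	201.1222	6.32	FALSE	FALSE
18	cyclo(Leu-Pro)	C11H18N2O2	211.1436	18.79	TRUE	FALSE
19	cyclo(Ile-Pro)	C11H18N2O2	211.1441	17.99	FALSE	FALSE
20	cyclo(Leu-Pro)	C11H18N2O2	211.1447	19.16	TRUE	FALSE
21	cyclo(Asn-Pro)	C9H13N3O3	212.1040	2.24	FALSE	FALSE
22	cyclo(Val-Leu)	C11H20N2O2	213.1594	23.37	FALSE	FALSE
23	cyclo(Asn-Val)	C9H15N3O3	214.1181	2.90	FALSE	FALSE
24	cyclo(Asp-Val)	C9H14N2O4	215.1020	7.26	TRUE	FALSE
25	cyclo(Asp-Val)	C9H14N2O4	215.1030	9.41	TRUE	FALSE
26	cyclo(Glu-Pro)	C10H14N2O4	227.1013	6.47	TRUE	FALSE
27	cyclo(Glu-Pro)	C10H14N2O4	227.1025	7.64	TRUE	FALSE
28	cyclo(Leu-Hyp)	C11H18N2O3	227.1385	14.50	TRUE	FALSE
29	cyclo(Leu-Hyp)	C11H18N2O3	227.1387	15.15	TRUE	FALSE
30	cyclo(Asn-Ile)	C10H17N3O3	228.1343	6.09	FALSE	FALSE
31	cyclo(Asn-Leu)	C10H17N3O3	228.1343	6.70	FALSE	FALSE
32	cyclo(Asp-Ile)	C10H16N2O4	229.1171	12.13	TRUE	FALSE
33	cyclo(Asp-Ile)	C10H16N2O4	229.1174	11.53	TRUE	FALSE
34	cyclo(MeEGlu-Pro)	C11H16N2O4	241.1180	11.88	TRUE	FALSE
35	cyclo(MeEGlu-Pro)	C11H16N2O4	241.1181	13.12	TRUE	FALSE
36	cyclo(Glu-Leu)	C11H18N2O4	243.1330	17.17	TRUE	FALSE
37	cyclo(Glu-Leu)	C11H18N2O4	243.1330	18.51	TRUE	FALSE
38	cyclo(MeEGlu-Val)	C11H18N2O4	243.1332	16.45	FALSE	FALSE
39	cyclo(Glu-Ile)	C11H18N2O4	243.1335	14.83	FALSE	FALSE
40	cyclo(Phe-Pro)	C14H16N2O2	245.1280	22.23	FALSE	FALSE
41	cyclo(MeEGlu-Hyp)	C11H16N2O3	257.1123	8.80	FALSE	TRUE
42	cyclo(MeEGlu-Ile)	C12H20N2O4	257.1486	23.26	TRUE	TRUE
43	cyclo(MeEGlu-Ile)	C12H20N2O4	257.1492	20.82	TRUE	TRUE
44	cyclo(Phe-Hyp)	C11H18N2O3	261.1230	16.84	TRUE	FALSE
45	cyclo(Tyr-Pro)	C14H16N2O3	261.1237	13.31	FALSE	FALSE
46	cyclo(Phe-Hyp)	C11H18N2O3	261.1240	17.80	TRUE	FALSE
47	cyclo(PyroGlu-Tyr)	C14H14N2O4	275.1037	11.45	FALSE	TRUE
48	cyclo(Tyr-Hyp)	C14H16N2O4	277.1171	12.43	TRUE	FALSE
49	cyclo(Tyr-Hyp)	C14H16N2O4	277.1178	12.10	TRUE	FALSE
50	cyclo(Glu-Phe)	C14H16N2O4	277.1178	20.30	FALSE	FALSE
51	cyclo(Tyr-Asp)	C13H14N2O5	279.1332	10.06	FALSE	FALSE
52	cyclo(Glu-Tyr)	C14H16N2O5	293.1119	10.26	TRUE	FALSE
53	cyclo(Glu-Tyr)	C14H16N2O5	293.1122	11.43	TRUE	FALSE
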