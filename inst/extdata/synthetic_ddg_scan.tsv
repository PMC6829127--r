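position	sub	ddg	source
1	P	1.27	synthetic_example_P_scan
2	P	-0.17	synthetic_example_P_scan
3	P	0.93	synthetic_example_P_scan
4	P	0.72	synthetic_example_P_scan
5	P	0.2	synthetic_example_P_scan
6	P	-1.46	synthetic_example_P_scan
7	P	0.14	synthetic_example_P_scan
8	P	-0.12	synthetic_example_P_scan
9	P	0.9	synthetic_example_P_scan
10	P	0.37	synthetic_example_P_scan
11	P	0.43	synthetic_example_P_scan
12	P	0.14	synthetic_example_P_scan
13	P	0.6	synthetic_example_P_scan
14	P	0.6	synthetic_example_P_scan
15	P	-1.49	synthetic_example_P_scan
16	P	2.01	synthetic_example_P_scan
17	P	1.35	synthetic_example_P_scan
18	P	1	synthetic_example_P_scan
19	P	0.08	synthetic_example_P_scan
20	P	1.42	synthetic_example_P_scan
21	P	0.5	synthetic_example_P_scan
22	P	0.65	synthetic_example_P_scan
23	P	-0.45	synthetic_example_P_scan
24	P	2.12	synthetic_example_P_scan
25	P	0.84	synthetic_example_P_scan
26	P	2.52	synthetic_example_P_scan
27	P	2.36	synthetic_example_P_scan
28	P	0.85	synthetic_example_P_scan
29	P	1.38	synthetic_example_P_scan
30	P	2.35	synthetic_example_P_scan
31	P	0.32	synthetic_example_P_scan
32	P	0.95	synthetic_example_P_scan
33	P	0.57	synthetic_example_P_scan
34	P	1.1	synthetic_example_P_scan
35	P	0.96	synthetic_example_P_scan
36	P	1.85	synthetic_example_P_scan
37	P	1.33	synthetic_example_P_scan
38	P	0	synthetic_example_P_scan
39	P	1.32	synthetic_example_P_scan
40	P	0.06	synthetic_example_P_scan
1	A	-0.51	synthetic_example_A_scan
2	A	0.84	synthetic_example_A_scan
3	A	-0.54	synthetic_example_A_scan
4	A	0.51	synthetic_example_A_scan
5	A	-0.28	synthetic_example_A_scan
6	A	1.29	synthetic_example_A_scan
7	A	0.8	synthetic_example_A_scan
8	A	0.02	synthetic_example_A_scan
9	A	0.86	synthetic_example_A_scan
10	A	0.6	synthetic_example_A_scan
11	A	-0.52	synthetic_example_A_scan
12	A	0.16	synthetic_example_A_scan
13	A	-0.35	synthetic_example_A_scan
14	A	0.61	synthetic_example_A_scan
15	A	-0.15	synthetic_example_A_scan
16	A	0.14	synthetic_example_A_scan
17	A	-0.57	synthetic_example_A_scan
18	A	-0.37	synthetic_example_A_scan
19	A	0.39	synthetic_example_A_scan
20	A	-0.4	synthetic_example_A_scan
21	A	0.2	synthetic_example_A_scan
22	A	0.42	synthetic_example_A_scan
23	A	0.16	synthetic_example_A_scan
24	A	0.1	synthetic_example_A_scan
25	A	-0.91	synthetic_example_A_scan
26	A	0.11	synthetic_example_A_scan
27	A	-0.96	synthetic_example_A_scan
28	A	1.11	synthetic_example_A_scan
29	A	-0.4	synthetic_example_A_scan
30	A	0.4	synthetic_example_A_scan
31	A	0.66	synthetic_example_A_scan
32	A	0.3	synthetic_example_A_scan
33	A	1.24	synthetic_example_A_scan
34	A	-0.29	synthetic_example_A_scan
35	A	0.61	synthetic_example_A_scan
36	A	-0.38	synthetic_example_A_scan
37	A	1.79	synthetic_example_A_scan
38	A	0.78	synthetic_example_A_scan
39	A	0.06	synthetic_example_A_scan
40	A	0.85	synthetic_example_A_scan
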