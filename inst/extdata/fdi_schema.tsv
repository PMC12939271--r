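class_index	fdi_code
1	11
2	12
3	13
4	14
5	15
6	16
7	17
8	18
9	21
10	22
11	23
12	24
13	25
14	26
15	27
16	28
17	31
18	32
19	33
20	34
21	35
22	36
23	37
24	38
25	41
26	42
27	43
28	44
29	45
30	46
31	47
32	48
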