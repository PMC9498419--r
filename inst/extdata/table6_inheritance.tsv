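test_id	consistent_144	inconsistent_144	consistent_120	inconsistent_120
Trio_1	142	2	120	0
Trio_2	139	5	120	0
Trio_3	142	2	120	0
Trio_4	143	1	120	0
Trio_5	143	1	120	0
Trio_6	143	1	120	0
Trio_7	141	3	120	0
Trio_8	141	3	120	0
Trio_9	143	1	120	0
Trio_10	140	4	120	0
Trio_11	140	4	120	0
Trio_12	141	3	120	0
Trio_13	141	3	120	0
Trio_14	141	3	120	0
Trio_15	143	1	120	0
Trio_16	141	3	120	0
Trio_17	144	0	120	0
Trio_18	140	4	120	0
Trio_19	141	3	120	0
Trio_20	143	1	120	0
Trio_21	144	0	120	0
Trio_22	142	2	120	0
Trio_23	142	2	120	0
Trio_24	142	2	120	0
Trio_25	142	2	120	0
Trio_26	142	2	120	0
Trio_27	141	3	120	0
Trio_28	141	3	120	0
Trio_29	141	3	120	0
Pseudo-Trio_1	108	36	91	29
Pseudo-Trio_2	110	34	88	32
Pseudo-Trio_3	112	32	91	29
Pseudo-Trio_4	111	33	93	27
Pseudo-Trio_5	108	36	90	30
Half-pseudo-Trio_1	123	21	102	18
Half-pseudo-Trio_2	110	34	95	25
Half-pseudo-Trio_3	119	25	99	21
Half-pseudo-Trio_4	116	28	97	23
Half-pseudo-Trio_5	126	18	105	15
Parent-Foal_1	143	1	120	0
Parent-Foal_2	144	0	120	0
Parent-Foal_3	142	2	120	0
Parent-Foal_4	143	1	120	0
Parent-Foal_5	144	0	120	0
Pseudo-parent-Foal_1	132	12	109	11
Pseudo-parent-Foal_2	128	16	108	12
Pseudo-parent-Foal_3	131	13	110	10
Pseudo-parent-Foal_4	132	12	110	10
Pseudo-parent-Foal_5	136	8	114	6
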