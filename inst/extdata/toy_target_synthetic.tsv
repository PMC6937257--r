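gene	t1	t2	t3	t4	t5	t6	t7	t8	t9	t10	t11	t12
g1	5	10	2	5	6	6	5	2	6	4	8	0
g2	1	1	1	0	1	4	5	1	8	7	13	8
g3	0	0	0	0	4	4	5	8	1	1	3	4
g4	3	2	1	2	4	3	3	4	7	9	7	12
g5	1	1	1	4	5	1	2	4	5	6	3	7
g6	9	9	11	9	1	0	1	5	6	4	4	8
g7	5	1	1	0	0	0	1	1	2	9	5	4
g8	2	2	4	6	6	1	2	3	2	4	4	4
g9	0	0	1	1	9	3	2	4	5	3	2	1
g10	0	0	0	0	11	12	10	10	5	7	7	5
g11	1	1	2	2	5	3	4	8	2	1	1	1
g12	1	1	2	3	3	1	5	4	3	1	1	1
g13	0	1	0	0	0	0	0	0	4	2	2	4
g14	1	5	3	10	2	4	7	6	2	3	1	2
g15	4	4	4	4	3	0	6	1	1	1	0	0
g16	3	2	3	0	4	2	1	3	8	5	10	6
g17	8	13	13	14	4	5	4	7	4	2	4	0
g18	1	2	1	2	12	4	8	11	0	3	2	0
g19	3	2	4	2	2	4	0	4	3	7	1	1
g20	3	5	8	1	4	2	0	1	4	9	10	4
g21	6	5	7	7	1	3	1	1	4	5	3	3
g22	6	10	7	8	1	0	0	1	8	12	9	8
g23	7	1	8	6	5	12	6	11	6	3	1	3
g24	3	3	3	3	6	3	2	1	2	6	7	10
g25	3	5	1	1	9	8	14	13	2	0	1	2
g26	1	1	0	0	3	0	0	1	0	0	0	0
g27	4	6	3	3	7	5	3	2	9	5	3	2
g28	6	7	8	8	1	3	2	3	8	7	8	9
g29	0	1	0	1	7	9	11	5	3	4	3	3
g30	5	5	4	9	2	1	7	3	12	8	11	15
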