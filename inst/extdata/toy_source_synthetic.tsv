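gene	s1	s2	s3	s4	s5	s6	s7	s8	s9	s10	s11	s12	s13	s14	s15	s16	s17	s18	s19	s20	s21	s22	s23	s24
g1	6	9	8	8	8	6	5	9	4	7	5	2	6	5	5	5	1	8	4	3	7	2	5	3
g2	1	0	0	2	0	0	0	1	4	3	0	0	2	2	2	0	13	7	7	16	6	8	12	9
g3	0	0	1	0	0	1	0	0	4	7	6	5	8	7	6	4	4	1	4	3	1	3	1	1
g4	3	1	0	1	1	3	4	1	3	5	4	0	4	1	4	3	12	18	6	13	16	8	6	7
g5	1	1	0	3	1	2	2	1	1	5	3	6	5	3	1	6	2	7	5	5	4	6	5	1
g6	17	11	7	8	8	11	6	9	4	3	3	1	3	0	3	0	5	5	5	5	1	10	3	5
g7	3	3	3	2	2	1	1	0	0	0	0	0	0	2	0	0	3	2	5	4	4	5	2	5
g8	1	2	11	3	0	3	3	5	4	3	3	3	4	3	1	4	4	3	2	3	6	4	4	1
g9	1	2	0	0	1	1	0	0	5	1	7	7	8	6	7	4	2	2	7	4	4	2	6	4
g10	1	0	0	1	1	0	2	1	9	9	9	8	5	8	8	10	4	8	8	4	8	4	6	9
g11	1	1	1	4	4	4	1	3	2	3	0	1	1	4	5	3	1	0	3	1	2	1	2	3
g12	1	2	1	6	2	0	2	0	3	2	6	3	2	6	3	1	3	3	3	8	6	7	6	3
g13	1	3	1	2	0	4	1	1	0	0	0	0	0	0	0	0	2	4	1	3	1	1	2	4
g14	5	5	3	6	5	1	3	8	2	5	3	3	7	1	2	2	3	6	3	0	1	3	1	3
g15	0	2	4	3	3	3	2	2	3	5	1	0	2	3	3	2	2	0	2	2	2	2	1	2
g16	1	4	2	0	4	2	1	3	3	3	4	4	0	2	3	2	7	12	5	8	8	7	13	11
g17	22	9	9	15	14	8	7	12	6	5	6	4	2	7	3	3	3	4	1	0	4	4	2	0
g18	1	2	3	1	2	2	4	5	7	9	9	7	9	6	5	6	0	2	0	6	3	1	2	2
g19	4	4	2	2	4	1	2	2	2	2	4	2	5	0	2	4	4	5	1	4	6	6	3	3
g20	5	5	5	2	2	9	3	8	5	3	6	2	4	2	0	2	7	12	13	10	8	8	7	5
g21	10	9	7	4	10	7	11	7	2	1	2	0	1	0	1	1	1	1	5	8	2	3	6	4
g22	12	13	6	4	8	5	10	5	1	1	2	1	0	0	0	1	5	7	9	10	8	8	5	8
g23	5	8	7	7	4	6	2	1	5	9	5	2	9	8	6	4	1	3	1	4	7	6	1	1
g24	2	2	4	4	1	4	1	0	3	3	5	4	7	1	5	3	4	7	9	4	4	4	5	7
g25	2	9	4	6	9	8	4	4	7	6	7	7	10	8	6	5	1	3	0	0	0	0	2	0
g26	1	1	5	1	2	2	1	4	1	1	1	1	1	2	1	1	0	1	0	0	0	1	1	1
g27	6	6	0	4	4	3	6	4	4	1	6	3	10	3	10	7	5	2	5	4	6	5	2	4
g28	8	8	12	12	8	8	9	9	1	1	2	4	3	4	1	5	7	9	7	14	11	9	9	9
g29	1	0	0	0	1	0	1	0	7	11	7	7	10	9	8	6	1	4	1	3	2	2	4	5
g30	10	6	9	4	1	3	7	5	4	3	5	2	4	5	3	2	9	6	5	11	6	5	6	7
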