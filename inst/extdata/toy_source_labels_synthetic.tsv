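cell_id	label
s1	0
s2	0
s3	0
s4	0
s5	0
s6	0
s7	0
s8	0
s9	1
s10	1
s11	1
s12	1
s13	1
s14	1
s15	1
s16	1
s17	2
s18	2
s19	2
s20	2
s21	2
s22	2
s23	2
s24	2
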