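chain	res_name	res_index	e_total	e_elec	e_vdw	e_desolv	site
A	TYR	1	-1.6	-0.9	-1.4	0.7	II
A	LEU	5	-1.3	-0.2	-1.6	0.5	II
A	GLU	6	2.1	0.6	-0.4	1.9	II
A	LYS	8	-1.9	-1.5	-1.1	0.7	II
A	ASP	17	-4.2	-3.6	-1.5	0.9	I
A	PHE	21	-3.6	-0.4	-3.8	0.6	I
A	GLU	31	-1.5	-1.2	-0.8	0.5	I
A	ASP	32	-3.9	-3.3	-1.3	0.7	I
A	MET	33	-0.9	-0.1	-1.2	0.4	I
A	THR	34	-1.2	-0.5	-1.0	0.3	I
A	ASP	35	-1.8	-1.6	-0.7	0.5	I
A	ASP	37	-4.8	-4.1	-1.6	0.9	I
A	ASP	40	-3.4	-2.9	-1.2	0.7	I
A	ASN	41	0.8	0.3	-0.3	0.8	I
A	ARG	44	0.5	0.4	-0.5	0.6	I
A	LYS	53	-2.2	-1.8	-1.0	0.6	II
A	ASP	54	0.6	0.5	-0.4	0.5	II
A	SER	55	-1.1	-0.6	-0.8	0.3	II
A	GLN	56	0.4	0.2	-0.3	0.5	II
A	MET	60	-3.3	-0.3	-3.6	0.6	II
A	LYS	79	-0.08	-0.3	-0.4	0.62	III
A	LYS	84	-0.21	-0.4	-0.5	0.69	III
A	LYS	93	-0.95	-0.65	-0.6	0.3	I
A	ASP	98	0.32	0.4	-0.5	0.42	III
A	GLN	103	-1.2	-0.6	-0.9	0.3	II
A	ARG	104	-0.9	-0.7	-0.6	0.4	I
A	ASP	110	0.9	0.7	-0.4	0.6	II
A	ASN	111	1.1	0.6	-0.2	0.7	II
A	MET	113	0.3	0.1	-0.3	0.5	II
A	LYS	129	1.2	0.9	-0.3	0.6	I
A	ARG	131	1.5	1.1	-0.4	0.8	I
A	ASP	132	-2.1	-1.8	-0.8	0.5	I
A	LEU	133	-1.4	-0.1	-1.7	0.4	I
A	PHE	134	-3.1	-0.3	-3.4	0.6	I
A	ASN	155	0.2	0.1	-0.3	0.4	II
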