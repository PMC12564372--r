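variant	group	ddg_binding	ddg_fold_complex	ddg_fold_ligand	score_published
WT	control	0	0	0	0
E6K	control	-1.9	-0.6	0.3	1.95
T63A	control	-0.8	0.8	0.8	-0.44
M60Q	control	4.6	2.2	0.8	-5.35
M33Q	control	4.6	2.9	2.7	-7.02
E6M	single	-1.4	-1.7	-0.8	2.76
K129M	single	-3.0	-0.8	-0.1	2.74
R131K	single	-3.0	0.2	0.0	1.93
N111S	single	-1.2	-1.1	-0.3	1.87
R131G	single	-0.6	-0.9	-1.1	1.70
K129M+R131G	double	-2.0	-2.5	-2.1	4.48
E6M+R131G	double	-1.9	-2.6	-1.9	4.43
E6M+K129M	double	-2.3	-2.6	-0.9	4.02
E6M+N111S	double	-2.0	-2.6	-1.1	3.98
E6M+R131K	double	-3.4	-1.5	-0.7	3.94
N111S+R131G	double	-2.2	-1.9	-1.4	3.82
R131K+N111S	double	-4.0	-0.9	-0.2	3.63
K129M+N111S	double	-2.6	-2.0	-0.4	3.52
K129M+R131K	double	-2.4	-0.6	0.0	2.09
E6M+K129M+R131G+N111S	multiple	-5.4	-5.6	-3.2	9.78
E6M+N111S+R131G	multiple	-4.8	-4.0	-2.2	7.66
E6M+K129M+R131G	multiple	-3.7	-4.3	-2.9	7.45
K129M+N111S+R131G	multiple	-4.7	-3.8	-2.3	7.45
E6M+K129M+R131K+N111S	multiple	-4.8	-3.1	-1.1	6.35
E6M+R131K+N111S	multiple	-4.2	-2.3	-1.0	5.27
E6M+K129M+N111S	multiple	-2.3	-3.5	-1.2	4.88
E6M+K129M+R131K	multiple	-3.5	-2.3	-0.8	4.65
K129M+R131K+N111S	multiple	-3.9	-1.7	-0.3	4.13
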