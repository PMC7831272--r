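locus	condition	replicate	ct_chip	ct_input	input_fraction
PCK1	control	1	26.10	22.05	0.0625
PCK1	control	2	26.32	22.11	0.0625
PCK1	control	3	26.21	21.98	0.0625
PCK1	FLHS	1	24.05	22.02	0.0625
PCK1	FLHS	2	24.21	22.10	0.0625
PCK1	FLHS	3	24.12	21.95	0.0625
APOA1	control	1	25.40	21.90	0.0625
APOA1	control	2	25.52	22.01	0.0625
APOA1	control	3	25.46	21.94	0.0625
APOA1	FLHS	1	26.90	22.03	0.0625
APOA1	FLHS	2	27.05	21.97	0.0625
APOA1	FLHS	3	26.98	22.08	0.0625
ANGPTL4	control	1	27.10	22.00	0.0625
ANGPTL4	control	2	27.25	22.12	0.0625
ANGPTL4	control	3	27.18	22.04	0.0625
ANGPTL4	FLHS	1	25.60	21.99	0.0625
ANGPTL4	FLHS	2	25.72	22.06	0.0625
ANGPTL4	FLHS	3	25.66	22.01	0.0625
negctrl	control	1	30.10	22.00	0.0625
negctrl	control	2	30.22	22.05	0.0625
negctrl	control	3	30.15	21.98	0.0625
negctrl	FLHS	1	30.18	22.02	0.0625
negctrl	FLHS	2	30.09	22.07	0.0625
negctrl	FLHS	3	30.21	22.00	0.0625
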