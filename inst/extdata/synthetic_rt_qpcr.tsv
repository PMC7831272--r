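gene	condition	replicate	ct_target	ct_reference
PCK1	control	1	24.80	17.10
PCK1	control	2	24.95	17.05
PCK1	control	3	24.88	17.12
PCK1	FLHS	1	23.10	17.08
PCK1	FLHS	2	23.22	17.15
PCK1	FLHS	3	23.15	17.03
APOA1	control	1	21.40	17.06
APOA1	control	2	21.52	17.11
APOA1	control	3	21.45	17.02
APOA1	FLHS	1	22.85	17.09
APOA1	FLHS	2	22.97	17.14
APOA1	FLHS	3	22.90	17.05
KIT	control	1	27.60	17.04
KIT	control	2	27.74	17.10
KIT	control	3	27.66	17.07
KIT	FLHS	1	26.30	17.12
KIT	FLHS	2	26.42	17.01
KIT	FLHS	3	26.35	17.08
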