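complex	component	mean	sd
binary	ele	-10765.22	61.14
binary	vdw	-330.00	11.10
binary	np	-48.51	0.18
binary	polar	11002.22	62.58
binary	ele_polar	237.00	18.12
binary	dH	-141.51	17.61
binary	TdS	-123.14	30.43
binary	dG	-18.37	8.01
binary	experiment	-13.67	NA
ternary	ele	-1739.81	40.55
ternary	vdw	-187.51	9.76
ternary	np	-29.72	0.56
ternary	polar	1844.13	35.63
ternary	ele_polar	104.31	14.99
ternary	dH	-112.91	11.26
ternary	TdS	-82.99	25.53
ternary	dG	-29.92	7.60
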