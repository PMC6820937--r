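name: pima-t2dm-2019
link: log
scaling: age=10, hba1c=1, fpg=100, scr=1
sex	scr_lo	scr_hi	intercept	age	hba1c	fpg	scr
F	0	0.55	4.8623	-0.1377	0.0290	0.0607	-0.0360
F	0.55	0.62	4.8435	-0.1178	0.0268	0.0480	-0.0039
F	0.62	0.72	4.7982	-0.1104	0.0306	0.0417	-0.1263
F	0.72	Inf	4.7916	-0.0928	-0.0014	0.0671	-0.2460
M	0	0.70	4.9756	-0.0752	0.0357	0.0259	-0.1160
M	0.70	0.79	4.9666	-0.1075	0.0110	0.0634	-0.2750
M	0.79	0.90	4.976	-0.1406	-0.0385	0.0074	-0.1463
M	0.90	Inf	5.0159	-0.1235	0.0328	-0.0236	-0.1771
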