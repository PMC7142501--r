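equation_id	source	response	predicted_mean	actual_mean	mpe	se	r2	rc	resid_mean	resid_sd	resid_min	resid_max
AN	zhao	ME	10.14	9.89	0.043	0.367	0.22	0.29	0.168	1.559	-2.80	2.48
AO	nrc	ME	9.31	9.89	0.042	0.156	0.90	0.31	-0.661	0.661	-1.90	0.69
AP	arc	ME	9.74	9.89	0.054	0.128	0.90	0.43	-0.227	0.545	-0.93	1.10
AQ	afrc	ME	10.00	9.89	0.062	0.259	0.62	0.27	0.032	1.098	-2.54	2.10
AR	givens	ME	9.85	9.89	0.083	0.242	0.64	0.37	-0.125	1.028	-2.42	2.15
AS	givens	ME	10.29	9.89	0.053	0.322	0.55	0.59	0.317	1.364	-2.27	2.31
AT	givens	ME	10.22	9.89	0.051	0.428	0.11	0.48	0.247	1.814	-3.55	3.14
AU	terry	ME	9.40	9.89	0.052	0.148	0.90	0.39	-0.574	0.626	-1.77	0.78
AV	terry	ME	9.24	9.89	0.072	0.241	0.64	0.57	-0.732	1.021	-2.93	1.61
AW	stergiadis	ME	9.37	9.89	0.054	0.556	0.30	0.62	-0.606	2.357	-4.83	3.16
AX	stergiadis	ME	9.34	9.89	0.082	0.248	0.62	0.42	-0.630	1.050	-3.10	1.54
AY	stergiadis	ME	9.78	9.89	0.062	0.186	0.81	0.67	-0.192	0.789	-1.24	1.52
AZ	stergiadis	ME	9.80	9.89	0.051	0.168	0.90	0.64	-0.171	0.714	-1.60	1.19
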