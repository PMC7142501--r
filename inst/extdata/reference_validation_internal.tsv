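equation_id	response	predicted_mean	actual_mean	mpe	se	r2	rc	resid_mean	resid_sd	resid_min	resid_max
A	DE	11.71	11.53	0.010	0.003	0.91	0.89	0.179	0.645	-1.142	1.546
B	DE	11.54	11.53	0.015	0.002	0.83	0.91	0.008	0.876	-1.948	1.553
C	DE	11.46	11.53	0.014	0.003	0.79	0.87	-0.074	0.976	-2.638	1.446
D	DE	11.53	11.53	0.011	0.003	0.91	0.92	0.180	0.741	-1.045	2.063
E	DE	11.67	11.53	0.012	0.003	0.90	0.78	0.136	0.772	-0.812	2.128
F	DE	11.46	11.53	0.011	0.002	0.92	0.83	-0.073	0.643	-1.032	1.194
G	DE	11.53	11.53	0.015	0.002	0.90	0.88	-0.299	0.737	-1.429	1.108
H	DE	11.49	11.53	0.013	0.002	0.89	0.84	-0.045	0.782	-1.747	1.571
I	ME	10.14	9.89	0.022	0.008	0.90	0.79	0.251	0.745	-0.823	1.930
J	ME	9.97	9.89	0.027	0.008	0.84	0.91	0.085	0.998	-1.810	1.851
K	ME	10.06	9.89	0.025	0.009	0.79	0.87	0.168	0.862	-1.467	2.161
L	ME	9.59	9.89	0.012	0.002	0.84	0.71	-0.301	0.681	-2.123	0.657
M	ME	9.91	9.89	0.053	0.012	0.86	0.75	0.023	0.854	-0.661	2.371
N	ME	10.70	9.89	0.036	0.012	0.84	0.69	0.807	0.559	-0.075	2.048
O	ME	9.02	9.89	0.053	0.005	0.83	0.65	-0.872	0.694	-1.935	0.490
P	ME	9.98	9.89	0.040	0.005	0.90	0.86	0.095	0.425	0.149	1.646
Q	ME	9.96	9.89	0.020	0.009	0.95	0.77	0.068	0.716	-0.870	2.081
R	ME	8.96	9.89	0.019	0.009	0.95	0.68	0.067	0.730	-0.831	2.048
S	ME	9.95	9.89	0.018	0.009	0.95	0.74	0.060	0.680	-0.682	1.777
T	ME	9.95	9.89	0.019	0.010	0.93	0.81	0.060	0.803	-1.121	2.228
U	ME	9.94	9.89	0.018	0.009	0.95	0.74	0.055	0.674	-0.843	1.754
V	ME	10.12	9.89	0.067	0.008	0.87	0.71	0.124	0.662	-0.826	1.504
W	ME	9.81	9.89	0.071	0.008	0.85	0.69	-0.080	0.676	-0.906	1.151
X	ME/GE	0.62	0.62	0.018	0.006	0.71	0.90	-0.006	0.063	-0.072	0.195
Y	ME/GE	0.62	0.62	0.012	0.005	0.86	0.91	0.008	0.044	-0.047	0.148
Z	ME/GE	0.62	0.62	0.061	0.004	0.91	0.89	0.006	0.036	-0.083	0.110
AA	ME/GE	0.62	0.62	0.014	0.005	0.74	0.78	-0.001	0.062	-0.159	0.172
AB	ME/GE	0.62	0.62	0.016	0.006	0.79	0.92	0.001	0.057	-0.096	0.187
AC	ME/GE	0.62	0.62	0.012	0.004	0.86	0.93	-0.005	0.047	-0.065	0.153
AD	ME/GE	0.62	0.62	0.012	0.004	0.88	0.94	0.003	0.043	-0.045	0.145
AE	ME/GE	0.62	0.62	0.013	0.004	0.78	0.91	0.002	0.056	-0.126	0.178
AF	DE/GE	0.64	0.64	0.024	0.005	0.92	0.73	-0.010	0.032	-0.061	0.040
AG	DE/GE	0.64	0.64	0.015	0.003	0.94	0.69	0.001	0.027	-0.030	0.088
AH	DE/GE	0.64	0.64	0.014	0.005	0.88	0.89	-0.004	0.040	-0.068	0.097
AI	DE/GE	0.64	0.64	0.013	0.004	0.93	0.88	-0.003	0.041	-0.064	0.087
AJ	DE/GE	0.64	0.64	0.013	0.004	0.95	0.75	0.002	0.031	-0.063	0.060
AK	DE/GE	0.64	0.64	0.016	0.005	0.91	0.69	-0.004	0.040	-0.049	0.115
AL	DE/GE	0.64	0.64	0.011	0.004	0.95	0.79	-0.004	0.032	-0.078	0.058
AM	DE/GE	0.64	0.64	0.012	0.003	0.95	0.87	-0.005	0.040	-0.062	0.091
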