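gene	stage	beta_0	beta_1	beta_2	beta_3	beta_4	adj_p_contrast	adj_p_control	status
CHRNA6	I	-1.67	3.35	2.85	2.93	2.21	2.25e-52	7.59e-51	Up
MMP10	I	0.04	3.19	2.76	2.61	1.68	5.07e-23	1.66e-24	Up
DEPDC1	II	2.01	2.83	3.32	3.03	2.43	3.26e-92	1.39e-89	Up
COX7A1	II	2.36	-2.31	-2.62	-2.30	-2.03	3.15e-72	4.39e-69	Down
KCNK15	III	1.99	2.40	1.85	2.59	1.72	8.24e-21	5.27e-20	Up
MFSD4	III	1.56	-2.06	-1.96	-2.32	-1.79	4.51e-41	2.88e-41	Down
CDH19	III	-3.13	-2.60	-2.58	-3.19	-2.61	3.31e-26	1.53e-24	Down
CXCL5	III	-2.03	-2.47	-2.17	-2.87	-2.83	5.12e-24	1.30e-22	Down
AKR7A3	III	3.26	2.05	1.52	2.33	2.12	1.83e-13	2.55e-12	Up
DEGS2	III	4.82	2.60	2.02	2.69	2.27	9.30e-22	1.68e-21	Up
CST2	III	-0.60	4.18	3.57	4.22	3.52	2.19e-48	8.75e-52	Up
LOC100124692	III	-2.52	-3.64	-3.60	-4.13	-3.83	2.98e-46	8.24e-48	Down
GDF5	III	-1.26	-2.08	-2.31	-2.63	-2.24	1.67e-26	3.64e-26	Down
FOXA1	III	7.19	2.09	1.64	2.32	1.94	4.81e-13	1.30e-11	Up
EGR3	IV	4.14	-2.33	-2.71	-2.57	-4.04	3.53e-18	1.46e-44	Down
FOS	IV	7.27	-2.44	-3.07	-3.09	-4.19	3.40e-21	3.50e-62	Down
FOSB	IV	4.71	-3.80	-4.33	-4.30	-5.66	9.16e-25	4.51e-76	Down
DUSP1	IV	7.00	-2.13	-2.40	-2.23	-3.13	2.51e-19	1.81e-58	Down
FREM1	IV	0.85	-3.67	-4.13	-3.70	-5.09	1.29e-23	2.43e-77	Down
EGR1	IV	7.45	-2.72	-3.18	-3.11	-4.00	3.63e-23	2.23e-75	Down
HFM1	IV	-3.44	-2.02	-2.24	-2.23	-3.02	6.13e-18	1.43e-52	Down
ABCA10	IV	-0.28	-4.38	-4.80	-4.48	-5.67	5.63e-33	3.89e-115	Down
KLK5	IV	1.26	-3.21	-3.44	-3.44	-5.45	6.93e-20	2.41e-09	Down
KCNA1	IV	-1.69	-2.58	-2.99	-2.81	-3.93	3.08e-15	1.99e-45	Down
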