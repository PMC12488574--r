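gene	beta_1	beta_2	beta_3	beta_4	adj_p	status
NEK2	4.34	4.83	4.65	4.82	1.37e-188	Up
MMP11	5.94	5.75	5.96	6.43	3.80e-173	Up
PKMYT1	4.42	4.83	4.73	4.90	1.60e-172	Up
GPAM	-3.57	-3.68	-3.65	-3.85	9.39e-171	Down
CPA1	-4.34	-4.56	-4.28	-4.21	6.39e-170	Down
COL10A1	7.04	6.74	6.95	7.22	3.43e-169	Up
MYOC	-6.06	-6.55	-6.34	-7.17	1.06e-166	Down
KIF4A	4.05	4.54	4.33	4.55	1.61e-164	Up
CA4	-6.63	-7.35	-6.91	-7.11	2.01e-162	Down
LYVE1	-4.76	-5.19	-4.90	-4.91	5.79e-159	Down
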