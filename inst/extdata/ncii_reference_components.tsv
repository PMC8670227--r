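population	trait	mean	sd	cv_published	sigma2_G	sigma2_GxE	sigma2_eps	n_env	n_rep	H2_published
RIL	PH	179.28	15.29	8.53	217.97	26.64	45.08	4	2	0.95
RIL	EH	67.87	8.91	13.13	73.83	9.39	17.18	4	2	0.94
RIL	VW	640.84	32.39	5.05	606.28	399.41	2026.25	5	2	0.68
TC	VW	555.35	21.81	3.93	252.96	143.69	1238.20	4	2	0.57
TC	GY	131.15	9.68	7.38	53.37	35.86	235.67	5	2	0.63
TM	GY	125.65	8.74	6.95	40.76	45.49	180.99	5	2	0.60
TM	PH	259.11	8.61	3.32	65.16	15.32	31.10	4	2	0.89
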