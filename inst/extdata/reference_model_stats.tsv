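model	endpoint	set	n	r2	ccc	iic	q2	q2f3	rmse	mae	f
general	NOAEL	active_training	140	0.51	0.67	0.64	0.50	NA	0.72	0.60	142
general	NOAEL	passive_training	140	0.51	0.69	0.65	0.50	NA	0.81	0.69	142
general	NOAEL	calibration	140	0.56	0.71	0.75	0.54	0.82	0.47	0.37	174
general	NOAEL	validation	141	0.55	0.69	0.56	NA	0.53	0.65	0.45	172
general	LOAEL	active_training	142	0.55	0.71	0.70	0.54	NA	0.66	0.50	173
general	LOAEL	passive_training	142	0.55	0.68	0.51	0.53	NA	0.72	0.57	168
general	LOAEL	calibration	137	0.51	0.63	0.71	0.49	0.48	0.71	0.56	138
general	LOAEL	validation	137	0.53	0.63	0.59	NA	0.32	0.72	0.53	149
kidney	NOAEL	active_training	95	0.50	0.67	0.67	0.48	NA	0.56	0.48	94
kidney	NOAEL	passive_training	95	0.52	0.54	0.57	0.51	NA	0.73	0.64	103
kidney	NOAEL	calibration	45	0.62	0.78	0.78	0.58	0.86	0.32	0.27	70
kidney	NOAEL	validation	45	0.59	0.75	0.70	NA	0.84	0.33	0.27	62
kidney	LOAEL	active_training	97	0.51	0.68	0.62	0.49	NA	0.51	0.40	99
kidney	LOAEL	passive_training	102	0.59	0.58	0.72	0.57	NA	0.52	0.44	143
kidney	LOAEL	calibration	46	0.67	0.81	0.82	0.63	0.77	0.35	0.28	88
kidney	LOAEL	validation	38	0.69	0.82	0.66	NA	0.81	0.31	0.25	80
brain	NOAEL	active_training	23	0.55	0.71	0.57	0.46	NA	0.67	0.59	26
brain	NOAEL	passive_training	22	0.61	0.42	0.64	0.52	NA	0.75	0.68	31
brain	NOAEL	calibration	23	0.58	0.74	0.76	0.51	0.88	0.31	0.26	28
brain	NOAEL	validation	22	0.53	0.67	0.68	NA	0.81	0.35	0.28	23
brain	LOAEL	active_training	22	0.54	0.70	0.51	0.44	NA	0.61	0.55	23
brain	LOAEL	passive_training	23	0.69	0.42	0.83	0.61	NA	0.91	0.82	48
brain	LOAEL	calibration	22	0.66	0.76	0.81	0.59	0.84	0.34	0.30	39
brain	LOAEL	validation	23	0.69	0.80	0.80	NA	0.82	0.33	0.26	46
liver	NOAEL	active_training	97	0.76	0.86	0.72	0.75	NA	0.38	0.29	297
liver	NOAEL	passive_training	94	0.73	0.83	0.78	0.72	NA	0.44	0.34	247
liver	NOAEL	calibration	30	0.78	0.83	0.89	0.75	0.82	0.35	0.28	103
liver	NOAEL	validation	31	0.55	0.73	0.54	NA	0.55	0.54	0.38	35
liver	LOAEL	active_training	96	0.78	0.87	0.78	0.77	NA	0.32	0.23	326
liver	LOAEL	passive_training	95	0.78	0.81	0.65	0.77	NA	0.40	0.32	323
liver	LOAEL	calibration	30	0.76	0.84	0.87	0.72	0.71	0.38	0.28	89
liver	LOAEL	validation	31	0.61	0.71	0.61	NA	0.55	0.48	0.40	46
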