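index	units	mean_control	se_control	mean_W	se_W	mean_N	se_N	mean_NW	se_NW
SOM content	g/kg soil	10.30	0.94	10.00	1.18	12.62	1.14	12.00	0.59
Soil total N content	g/kg soil	2.72	0.15	2.70	0.14	2.50	0.07	2.50	0.01
Soil available N content	mg/kg soil	13.47	0.92	19.68	1.61	26.39	2.62	25.88	6.03
Soil water content	kg/kg soil	0.07	0.01	0.11	0.01	0.07	0.01	0.11	0.01
Soil pH	unitless	7.22	0.07	7.32	0.10	6.43	0.03	6.78	0.17
Aboveground plant biomass	g/m2	45.93	13.02	46.38	1.93	47.67	5.18	77.58	15.36
Plant species richness	count	11.25	0.48	14.25	1.44	9.50	0.65	11.75	1.65
Bacterial 16S rRNA gene abundance	1e10/g soil	1.11	0.15	1.10	0.14	0.91	0.11	1.22	0.15
Bacterial relative abundance	%	93.59	0.52	95.03	0.34	93.65	0.18	94.04	0.27
Archaeal relative abundance	%	5.23	0.60	4.26	0.19	4.85	0.09	5.10	0.21
Fungal relative abundance	%	1.18	0.16	0.71	0.17	1.50	0.20	0.86	0.17
Microbial respiration	mg CO2/kg/day	40.56	1.07	43.39	0.97	36.71	1.06	42.20	1.16
Ammonia oxidization potential	NO2-N mg/g soil/h	1.52	0.60	1.27	0.44	9.48	0.90	8.91	1.08
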