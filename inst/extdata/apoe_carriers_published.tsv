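study	n	carriers_no_domain	carriers_memory	carriers_executive	carriers_language	carriers_visuospatial	carriers_multiple	carriers_overall	pct_no_domain	pct_memory	pct_executive	pct_language	pct_visuospatial	pct_multiple	pct_overall
ACT	711	134	51	11	14	27	6	243	35	46	24	24	30	32	34
ADNI	650	185	139	10	30	48	15	427	66	73	63	58	57	54	66
MAP	386	45	33	1	23	9	21	132	34	44	33	27	26	39	34
ROS	393	49	26	NA	31	26	11	143	35	48	NA	28	41	46	36
PITT	1561	283	411	15	72	97	39	917	54	70	65	44	57	44	59
Overall	3701	696	660	37	170	207	92	1861	48	65	42	36	47	43	50
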