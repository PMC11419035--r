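category	subcategory	kappa_complete	lambda_complete	total_complete	kappa_incomplete	lambda_incomplete	total_incomplete	kappa_fragment	lambda_fragment	total_fragment	total
AL-PCD	AL	160	524	684	34	63	97	6	35	41	822
AL-PCD	AL/MM	29	25	54	0	4	4	0	2	2	60
AL-PCD	AL/CLL	0	2	2	0	0	0	0	0	0	2
AL-PCD	AL/LCDD	1	0	1	0	0	0	0	0	0	1
AL-PCD	AL/WM	2	3	5	0	0	0	1	0	1	6
Other-PCD	MM	595	374	969	70	83	153	42	26	68	1190
Other-PCD	LCDD	29	4	33	3	0	3	2	4	6	42
Other-PCD	POEMS	0	31	31	0	5	5	0	13	13	49
Other-PCD	WM	5	0	5	0	0	0	8	0	8	13
Other-PCD	WM/LCDD	0	0	0	1	0	1	0	0	0	1
Other-PCD	Other	4	0	4	0	0	0	3	0	3	7
Non-PCD	Localized AL	0	1	1	1	2	3	0	2	2	6
Non-PCD	Non-PCD	1051	581	1632	621	346	967	102	34	136	2735
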