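source	df	SS	MS	F	p
Blocks	2	1.2927	0.6464		
Temperature	4	58.603	14.651	18.398	0.0004
Main-plot error	8	6.3707	0.7963		
Tissue	9	270.57	30.063	128.02	0
Temperature x Tissue	36	328.25	9.1181	38.83	0
Split-plot error	90	21.134	0.2348		
Gene	3	180.69	60.229	249.7	1e-07
Temperature x Gene	12	321.96	26.83	111.23	1e-07
Tissue x Gene	27	222.42	8.2378	34.153	1e-07
Temperature x Tissue x Gene	108	485.05	4.4912	18.62	1e-07
Split-split-plot error	300	72.361	0.2412		
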