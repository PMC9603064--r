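temperature	source	df	SS	MS	F	p	pct
14	Total	119	21.5253	0.1809			
14	Treatment	39	15.2082	0.39	4.9384	0	
14	Gene	3	0.0548	0.0183	0.2311	0.87444	0.2545
14	Tissue	9	5.9496	0.6611	8.3718	0	27.64
14	Interaction	27	9.2039	0.3409	4.317	0	42.7585
14	IPCA1	11	4.39599	0.39964	5.06101	6e-06	47.7622
14	IPCA2	9	3.2454	0.3606	4.56665	7.1e-05	35.2611
14	Residual	7	1.5625	0.22321			
14	Error	80	6.31709	0.07896			
20	Total	119	480.995	4.042			
20	Treatment	39	447.293	11.4691	27.2247	0	
20	Gene	3	47.154	15.718	37.3106	0	9.8034
20	Tissue	9	256.9	28.5444	67.7573	0	53.41
20	Interaction	27	143.239	5.3052	12.5931	0	29.7797
20	IPCA1	11	120.236	10.9305	25.9463	0	83.9403
20	IPCA2	9	17.053	1.89477	4.49772	8.5e-05	11.9052
20	Residual	7	5.9508	0.85011			
20	Error	80	33.702	0.42127			
23	Total	119	370.434	3.1129			
23	Treatment	39	347.314	8.9055	30.8149	0	
23	Gene	3	127.261	42.4204	146.784	0	34.3546
23	Tissue	9	74.5141	8.2793	28.6483	0	20.1153
23	Interaction	27	145.539	5.3903	18.6517	0	39.2886
23	IPCA1	11	95.9195	8.71996	30.1729	0	65.9065
23	IPCA2	9	37.9649	4.21832	14.5963	0	26.0857
23	Residual	7	11.6543	1.6649			
23	Error	80	23.12	0.289			
25	Total	119	524.157	4.4047			
25	Treatment	39	498.347	12.7781	39.6067	0	
25	Gene	3	195.432	65.1441	201.919	0	37.285
25	Tissue	9	133.402	14.8224	45.9432	0	25.4507
25	Interaction	27	169.512	6.2782	19.4598	0	32.34
25	IPCA1	11	132.551	12.0501	37.3501	0	78.1954
25	IPCA2	9	35.5725	3.9525	12.2511	0	20.9852
25	Residual	7	1.38891	0.19842			
25	Error	80	25.8101	0.32263			
28	Total	119	512.987	4.3108			
28	Treatment	39	500.778	12.8405	84.1362	0	
28	Gene	3	132.745	44.2483	289.934	0	25.8768
28	Tissue	9	128.053	14.2281	93.229	0	24.9622
28	Interaction	27	239.979	8.8881	58.2389	0	46.7808
28	IPCA1	11	224.367	20.397	133.65	0	93.4943
28	IPCA2	9	15.3029	1.70032	11.1412	0	6.3767
28	Residual	7	0.30941	0.0442			
28	Error	80	12.2092	0.15261			
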