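temperature	type	name	PCA1	PCA2	PCA3	Di
14	gene	PPARa1	0.3631	-0.3388	0.5799	0.7635
14	gene	PPARa2	-0.2853	-0.6881	-0.4031	0.847
14	gene	PPARb	-0.7873	0.5357	0.1337	0.9616
14	gene	PPARg	0.7094	0.4912	-0.3105	0.9171
14	tissue	brain	-0.1959	-0.1842	0.212	0.3424
14	tissue	gill	0.3742	0.2135	0.3533	0.5571
14	tissue	heart	-0.2033	0.0081	-0.0187	0.2043
14	tissue	intestine	0.0757	-0.3207	0.0136	0.3298
14	tissue	kidney	0.1718	-0.2942	0.1449	0.3703
14	tissue	liver	-0.7228	0.5105	-0.049	0.8863
14	tissue	muscle	-0.0716	-0.5338	-0.4938	0.7307
14	tissue	skin	0.2494	0.1629	-0.0821	0.309
14	tissue	spleen	0.2178	0.4764	-0.3899	0.653
14	tissue	stomach	0.6664	0.2204	-0.1291	0.7137
20	gene	PPARa1	1.0137	0.5744	0.8333	1.4325
20	gene	PPARa2	-0.5413	-1.2729	0.2258	1.4016
20	gene	PPARb	-1.9714	0.6681	-0.2492	2.0964
20	gene	PPARg	1.499	0.0304	-0.8098	1.7041
20	tissue	brain	-0.4701	-1.0778	-0.1075	1.1808
20	tissue	gill	-2.0521	-0.3423	0.468	2.1324
20	tissue	heart	-1.7196	0.6663	-0.5255	1.9176
20	tissue	intestine	-0.1222	0.0793	-0.0252	0.1479
20	tissue	kidney	0.0731	0.2832	0.8371	0.8867
20	tissue	liver	-0.1064	0.7261	0.2317	0.7696
20	tissue	muscle	0.037	0.2154	-0.1444	0.262
20	tissue	skin	-0.172	0.0282	0.0462	0.1803
20	tissue	spleen	-0.0496	-0.0232	0.3393	0.3437
20	tissue	stomach	0.0133	-0.1143	-0.2517	0.2767
23	gene	PPARa1	2.4252	-0.4588	0.0502	2.4687
23	gene	PPARa2	-1.0131	-0.5212	-1.1106	1.591
23	gene	PPARb	-1.2498	-0.6838	0.9882	1.7339
23	gene	PPARg	-0.1622	1.6639	0.0721	1.6734
23	tissue	brain	1.4789	-0.3157	0.4705	1.5838
23	tissue	gill	1.779	-0.651	-0.1629	1.9014
23	tissue	heart	0.9966	-0.4567	0.0363	1.0969
23	tissue	intestine	0.1985	0.0565	-0.2898	0.3558
23	tissue	kidney	0.1161	-0.4054	-0.0442	0.424
23	tissue	liver	0.644	0.4309	-1.2183	1.4438
23	tissue	muscle	1.2598	1.2849	0.3835	1.8399
23	tissue	skin	0.1683	-0.165	-0.4971	0.5502
23	tissue	spleen	0.1445	0.3581	0.062	0.3911
23	tissue	stomach	0.2155	0.9091	-0.0159	0.9345
25	gene	PPARa1	1.9616	-1.3496	0.1036	2.3833
25	gene	PPARa2	-1.7486	-0.1206	0.5524	1.8377
25	gene	PPARb	-1.2483	-0.4003	-0.6314	1.455
25	gene	PPARg	1.0353	1.8706	-0.0247	2.1382
25	tissue	brain	1.8721	-1.2646	0.3754	2.2902
25	tissue	gill	0.8757	0.5911	0.0162	1.0567
25	tissue	heart	1.4477	-0.3709	-0.5774	1.6021
25	tissue	intestine	0.3812	-0.4361	0.1814	0.607
25	tissue	kidney	0.4074	0.6864	-0.0198	0.7985
25	tissue	liver	0.0646	0.6955	0.4082	0.8091
25	tissue	muscle	1.2839	0.9041	0.0284	1.5706
25	tissue	skin	0.9093	0.445	-0.0753	1.0152
25	tissue	spleen	0.1557	0.552	-0.1217	0.5864
25	tissue	stomach	0.5938	0.9715	0.1387	1.147
28	gene	PPARa1	2.755	-0.2784	0.0241	2.7691
28	gene	PPARa2	-1.2142	-0.6114	0.3761	1.4105
28	gene	PPARb	-1.0348	-0.8981	-0.3546	1.4154
28	gene	PPARg	-0.5059	1.788	-0.045	1.8588
28	tissue	brain	2.7607	-0.7314	0.0951	2.8575
28	tissue	gill	0.7933	0.7247	-0.1139	1.0805
28	tissue	heart	1.1408	0.9294	-0.0646	1.4729
28	tissue	intestine	0.4358	0.2129	0.0948	0.4942
28	tissue	kidney	0.2706	0.2908	-0.0118	0.3974
28	tissue	liver	0.1054	0.7348	0.4034	0.8449
28	tissue	muscle	0.3547	0.1679	-0.1111	0.4079
28	tissue	skin	0.6312	0.2448	-0.1734	0.6989
28	tissue	spleen	-0.1638	1.0535	0.0795	1.0691
28	tissue	stomach	0.1145	0.8142	-0.1518	0.8362
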