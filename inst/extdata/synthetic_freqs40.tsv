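site	A	C	G	T
1	0.540697758307633	0	0.459302241692367	0
2	0	0.103000518369464	0.896999481630536	0
3	0	0.00228847795576841	0	0.997711522044232
4	0	0.0161534091024684	0.983846590897532	0
5	0.873636433252192	0	0	0.126363566747808
6	0.276573836279994	0	0	0.723426163720005
7	0	0.220738233660412	0	0.779261766339588
8	0.107284493717613	0	0	0.892715506282387
9	0.796767889678137	0.203232110321863	0	0
10	0	0	0.539764027488677	0.460235972511323
11	0	0.513560852388092	0	0.486439147611908
12	0.536189939171119	0.463810060828881	0	0
13	0.116209141323174	0.883790858676826	0	0
14	0.961246527609276	0.038753472390724	0	0
15	0.0900499507634357	0	0.909950049236564	0
16	0.891125475774349	0	0.108874524225651	0
17	0	0.185465325770451	0	0.814534674229549
18	0.797761224468219	0	0	0.202238775531781
19	0	0.0135105002881927	0	0.986489499711807
20	0.0255098487763479	0	0	0.974490151223652
21	0	0.815283126510772	0.184716873489228	0
22	0	0.276187609119757	0	0.723812390880243
23	0.10484714522101	0.89515285477899	0	0
24	0	0	0.993493104014046	0.00650689598595351
25	0	0	0.993454310900711	0.00654568909928873
26	0.993220757731351	0	0	0.00677924226864948
27	0.0116040165505599	0	0.98839598344944	0
28	0.941731262251138	0.0582687377488622	0	0
29	0	0.206912247394177	0	0.793087752605823
30	0	0.97569563687113	0.0243043631288704	0
31	0	0.0699084595451435	0	0.930091540454857
32	0	0	0.978844368996686	0.0211556310033139
33	0.829054937681121	0.170945062318878	0	0
34	0	0.0295366027656515	0.970463397234348	0
35	0	0.999326761947757	0.000673238052242727	0
36	0.90648837258004	0.09351162741996	0	0
37	1.1867618894598e-05	0	0	0.999988132381105
38	0	0.844534130488546	0	0.155465869511454
39	0.978573621089288	0	0.0214263789107121	0
40	0.971812321080377	0	0	0.0281876789196229
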