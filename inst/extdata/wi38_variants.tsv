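Position	Variant	Frequency	Coverage
41006	insG	1.00	299
41008	G > C	1.00	299
41208	C > T	0.62	627
41214	T > C	0.42	615
41273	T > G	0.25	541
41294	T > G	0.71	520
41310	delC	1.00	431
41560	delT	1.00	244
41574	C > T	0.31	236
41594	delT	0.97	233
41659	T > G	0.25	204
41663	insTCCTC	0.56	126
41665	delTCCCTCC	0.10	174
42255	C > G	1.00	679
42256	G > C	1.00	674
42329	C > A	0.10	288
42398	insC	0.98	521
42400	C > G	0.98	505
42418	insGCG	0.99	534
42451	insG	0.99	564
42455	insCG	0.99	559
42500	delA	0.99	562
42553	delGCGGTC	0.34	435
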