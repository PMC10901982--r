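snp_id	risk_allele	freq	weight
snp01	A	0.269	0.426
snp02	G	0.477	0.253
snp03	G	0.381	0.380
snp04	A	0.440	0.265
snp05	A	0.412	0.261
snp06	G	0.132	0.233
snp07	T	0.477	0.377
snp08	G	0.427	0.121
snp09	T	0.272	0.355
snp10	T	0.220	0.176
snp11	G	0.216	0.387
snp12	C	0.173	0.270
snp13	A	0.416	0.239
snp14	C	0.326	0.318
snp15	G	0.108	0.220
snp16	T	0.414	0.203
snp17	G	0.269	0.148
snp18	A	0.379	0.353
snp19	T	0.358	0.379
snp20	C	0.340	0.153
snp21	T	0.356	0.203
snp22	C	0.152	0.358
snp23	A	0.175	0.092
snp24	C	0.274	0.208
snp25	G	0.493	0.267
snp26	C	0.435	0.284
snp27	C	0.092	0.119
snp28	G	0.376	0.412
snp29	C	0.225	0.092
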