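removed_id	kept_id	similarity	len_removed	len_kept
LR00048	LR00046	      1	2018	2020
LR00050	LR00046	      1	2010	2020
LR00042	LR00041	      1	1971	1979
LR00382	LR00380	      1	1909	1918
LR00134	LR00133	      1	1777	1791
LR00164	LR00162	      1	1712	1724
LR00167	LR00162	      1	1711	1724
LR00033	LR00031	      1	1681	1686
LR00139	LR00138	      1	1619	1625
LR00142	LR00138	      1	1614	1625
LR00149	LR00148	      1	1611	1620
LR00248	LR00244	      1	1592	1602
LR00367	LR00366	      1	1542	1554
LR00339	LR00337	      1	1512	1523
LR00200	LR00195	      1	1444	1448
LR00198	LR00195	      1	1435	1448
LR00293	LR00292	      1	1384	1391
LR00101	LR00100	      1	1382	1388
LR00372	LR00371	      1	1381	1391
LR00156	LR00153	      1	1372	1379
LR00040	LR00036	      1	1370	1376
LR00107	LR00105	      1	1343	1353
LR00278	LR00277	      1	1338	1349
LR00205	LR00201	      1	1277	1285
LR00203	LR00201	      1	1275	1285
LR00029	LR00026	      1	1254	1268
LR00397	LR00393	      1	1249	1258
LR00401	LR00398	      1	1148	1158
LR00113	LR00110	      1	1076	1080
LR00301	LR00297	      1	1036	1046
LR00283	LR00282	      1	1028	1036
LR00286	LR00282	      1	1024	1036
LR00070	LR00068	      1	1010	1020
LR00261	LR00260	      1	976	982
LR00019	LR00017	      1	928	938
LR00185	LR00181	      1	899	909
LR00094	LR00091	      1	856	867
LR00255	LR00253	      1	800	806
LR00259	LR00253	      1	796	806
LR00257	LR00253	      1	794	806
LR00190	LR00186	      1	792	798
LR00125	LR00123	      1	720	730
LR00128	LR00123	      1	720	730
LR00078	LR00077	      1	638	643
LR00082	LR00077	      1	631	643
LR00303	LR00302	      1	603	609
LR00314	LR00311	      1	541	549
LR00312	LR00311	      1	539	549
LR00242	LR00239	      1	497	501
LR00179	LR00176	      1	386	389
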