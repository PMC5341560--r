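gene_id	contig_id	signature	n_events	support
LR00001	TRINITY_DN1_c0_g1_i1		0	4
LR00001	TRINITY_DN1_c0_g1_i1	excl:799-901	1	4
LR00009	TRINITY_DN2_c0_g1_i1		0	4
LR00013	TRINITY_DN3_c0_g1_i1		0	4
LR00013	TRINITY_DN3_c0_g1_i1	excl:611-910	1	4
LR00022	TRINITY_DN4_c0_g1_i1		0	4
LR00022	TRINITY_DN4_c0_g1_i1	excl:612-998	1	4
LR00031	TRINITY_DN5_c0_g1_i1		0	4
LR00036	TRINITY_DN6_c0_g1_i1		0	4
LR00041	TRINITY_DN7_c0_g1_i1		0	4
LR00046	TRINITY_DN8_c0_g1_i1		0	4
LR00046	TRINITY_DN8_c0_g1_i1	excl:1583-1710	1	4
LR00056	TRINITY_DN9_c0_g1_i1		0	4
LR00060	TRINITY_DN10_c0_g1_i1		0	4
LR00060	TRINITY_DN10_c0_g1_i1	excl:689-809	1	4
LR00060	TRINITY_DN10_c0_g1_i1	excl:810-1107	1	4
LR00073	TRINITY_DN11_c0_g1_i1		0	4
LR00073	TRINITY_DN11_c0_g1_i1	excl:164-294	1	4
LR00073	TRINITY_DN11_c0_g1_i1	excl:294-434	1	4
LR00087	TRINITY_DN12_c0_g1_i1		0	4
LR00091	TRINITY_DN13_c0_g1_i1		0	4
LR00096	TRINITY_DN14_c0_g1_i1		0	4
LR00096	TRINITY_DN14_c0_g1_i1	excl:285-483	1	4
LR00096	TRINITY_DN14_c0_g1_i1	excl:959-1192	1	4
LR00110	TRINITY_DN15_c0_g1_i1		0	4
LR00110	TRINITY_DN15_c0_g1_i1	excl:352-669	1	4
LR00119	TRINITY_DN16_c0_g1_i1		0	4
LR00119	TRINITY_DN16_c0_g1_i1	excl:281-449	1	4
LR00119	TRINITY_DN16_c0_g1_i1	excl:448-671	1	4
LR00133	TRINITY_DN17_c0_g1_i1		0	4
LR00133	TRINITY_DN17_c0_g1_i1	excl:303-469	1	4
LR00144	TRINITY_DN18_c0_g1_i1		0	4
LR00148	TRINITY_DN19_c0_g1_i1		0	4
LR00148	TRINITY_DN19_c0_g1_i1	excl:865-1106	1	4
LR00158	TRINITY_DN20_c0_g1_i1		0	4
LR00162	TRINITY_DN21_c0_g1_i1		0	4
LR00162	TRINITY_DN21_c0_g1_i1	excl:245-486	1	4
LR00172	TRINITY_DN22_c0_g1_i1		0	4
LR00172	TRINITY_DN22_c0_g1_i1	excl:237-482	1	4
LR00181	TRINITY_DN23_c0_g1_i1		0	4
LR00181	TRINITY_DN23_c0_g1_i1	excl:92-203	1	4
LR00191	TRINITY_DN24_c0_g1_i1		0	4
LR00195	TRINITY_DN25_c0_g1_i1		0	4
LR00195	TRINITY_DN25_c0_g1_i1	excl:1140-1311	1	4
LR00195	TRINITY_DN25_c0_g1_i1	excl:977-1140	1	4
LR00211	TRINITY_DN26_c0_g1_i1		0	4
LR00211	TRINITY_DN26_c0_g1_i1	excl:226-548	1	4
LR00211	TRINITY_DN26_c0_g1_i1	excl:673-1062	1	4
LR00223	TRINITY_DN27_c0_g1_i1		0	4
LR00223	TRINITY_DN27_c0_g1_i1	excl:1399-1719	1	4
LR00223	TRINITY_DN27_c0_g1_i1	excl:898-1262	1	4
LR00235	TRINITY_DN28_c0_g1_i1		0	4
LR00235	TRINITY_DN28_c0_g1_i1	excl:97-461	1	4
LR00244	TRINITY_DN29_c0_g1_i1		0	4
LR00249	TRINITY_DN30_c0_g1_i1		0	4
LR00249	TRINITY_DN30_c0_g1_i1	excl:681-819	1	4
LR00260	TRINITY_DN31_c0_g1_i1		0	4
LR00265	TRINITY_DN32_c0_g1_i1		0	4
LR00265	TRINITY_DN32_c0_g1_i1	excl:423-797	1	4
LR00273	TRINITY_DN33_c0_g1_i1		0	4
LR00277	TRINITY_DN34_c0_g1_i1		0	4
LR00277	TRINITY_DN34_c0_g1_i1	excl:891-1204	1	4
LR00288	TRINITY_DN35_c0_g1_i1		0	4
LR00292	TRINITY_DN36_c0_g1_i1		0	4
LR00292	TRINITY_DN36_c0_g1_i1	excl:370-715	1	4
LR00302	TRINITY_DN37_c0_g1_i1		0	4
LR00307	TRINITY_DN38_c0_g1_i1		0	4
LR00307	TRINITY_DN38_c0_g1_i1	excl:279-421	1	4
LR00307	TRINITY_DN38_c0_g1_i1	excl:421-565	1	4
LR00321	TRINITY_DN39_c0_g1_i1		0	4
LR00321	TRINITY_DN39_c0_g1_i1	excl:508-766	1	4
LR00321	TRINITY_DN39_c0_g1_i1	excl:766-947	1	4
LR00333	TRINITY_DN40_c0_g1_i1		0	4
LR00337	TRINITY_DN41_c0_g1_i1		0	4
LR00342	TRINITY_DN42_c0_g1_i1		0	4
LR00346	TRINITY_DN43_c0_g1_i1		0	4
LR00346	TRINITY_DN43_c0_g1_i1	excl:416-509	1	4
LR00346	TRINITY_DN43_c0_g1_i1	excl:509-771	1	4
LR00358	TRINITY_DN44_c0_g1_i1		0	4
LR00358	TRINITY_DN44_c0_g1_i1	excl:428-760	1	4
LR00366	TRINITY_DN45_c0_g1_i1		0	4
LR00366	TRINITY_DN45_c0_g1_i1	excl:1046-1144	1	4
LR00366	TRINITY_DN45_c0_g1_i1	excl:368-531	1	4
LR00380	TRINITY_DN46_c0_g1_i1		0	4
LR00380	TRINITY_DN46_c0_g1_i1	excl:959-1211	1	4
LR00389	TRINITY_DN47_c0_g1_i1		0	4
LR00393	TRINITY_DN48_c0_g1_i1		0	4
LR00398	TRINITY_DN49_c0_g1_i1		0	4
LR00398	TRINITY_DN49_c0_g1_i1	excl:433-681	1	4
LR00398	TRINITY_DN49_c0_g1_i1	excl:681-958	1	4
LR00411	TRINITY_DN50_c0_g1_i1		0	4
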