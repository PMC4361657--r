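CD14	synthetic CD14-lineage probe set (generated fixture, not biological annotation)	probe_0049	probe_0056	probe_0060	probe_0104	probe_0161	probe_0185	probe_0260	probe_0291	probe_0324	probe_0384	probe_0407	probe_0434	probe_0436	probe_0444	probe_0464	probe_0493	probe_0494	probe_0653	probe_0659	probe_0674	probe_0675	probe_0717	probe_0731	probe_0741	probe_0765	probe_0836	probe_0880	probe_0895	probe_0918	probe_0934	probe_0936	probe_0966	probe_1027	probe_1049	probe_1105	probe_1107	probe_1191	probe_1203	probe_1204	probe_1495	probe_1496	probe_1504	probe_1606	probe_1617	probe_1642	probe_1763	probe_1828	probe_1833	probe_1855	probe_1908
CD19	synthetic CD19-lineage probe set (generated fixture, not biological annotation)	probe_0051	probe_0089	probe_0119	probe_0121	probe_0148	probe_0150	probe_0164	probe_0169	probe_0181	probe_0315	probe_0448	probe_0488	probe_0530	probe_0533	probe_0570	probe_0591	probe_0598	probe_0611	probe_0676	probe_0704	probe_0767	probe_0832	probe_0846	probe_1095	probe_1115	probe_1157	probe_1303	probe_1401	probe_1408	probe_1438	probe_1447	probe_1452	probe_1491	probe_1503	probe_1517	probe_1534	probe_1564	probe_1571	probe_1595	probe_1607	probe_1623	probe_1650	probe_1660	probe_1678	probe_1714	probe_1784	probe_1889	probe_1918	probe_1947	probe_1973
CD4	synthetic CD4-lineage probe set (generated fixture, not biological annotation)	probe_0015	probe_0031	probe_0062	probe_0073	probe_0077	probe_0093	probe_0168	probe_0334	probe_0356	probe_0381	probe_0390	probe_0455	probe_0474	probe_0549	probe_0590	probe_0665	probe_0714	probe_0743	probe_0797	probe_0840	probe_0894	probe_0952	probe_0961	probe_1052	probe_1059	probe_1096	probe_1151	probe_1172	probe_1258	probe_1292	probe_1308	probe_1318	probe_1324	probe_1351	probe_1465	probe_1508	probe_1563	probe_1577	probe_1596	probe_1649	probe_1668	probe_1709	probe_1718	probe_1775	probe_1782	probe_1866	probe_1932	probe_1941	probe_1951	probe_1978
CD56	synthetic CD56-lineage probe set (generated fixture, not biological annotation)	probe_0005	probe_0020	probe_0042	probe_0069	probe_0115	probe_0132	probe_0133	probe_0141	probe_0177	probe_0264	probe_0281	probe_0294	probe_0320	probe_0492	probe_0514	probe_0595	probe_0633	probe_0724	probe_0727	probe_0750	probe_0754	probe_0793	probe_0828	probe_0944	probe_1103	probe_1163	probe_1192	probe_1207	probe_1217	probe_1253	probe_1320	probe_1354	probe_1392	probe_1416	probe_1421	probe_1457	probe_1474	probe_1477	probe_1497	probe_1537	probe_1543	probe_1662	probe_1683	probe_1761	probe_1765	probe_1776	probe_1792	probe_1899	probe_1920	probe_1966
CD66	synthetic CD66-lineage probe set (generated fixture, not biological annotation)	probe_0045	probe_0092	probe_0099	probe_0109	probe_0112	probe_0158	probe_0159	probe_0222	probe_0266	probe_0300	probe_0340	probe_0386	probe_0393	probe_0396	probe_0412	probe_0453	probe_0495	probe_0519	probe_0539	probe_0648	probe_0730	probe_0753	probe_0774	probe_0783	probe_0845	probe_0882	probe_0900	probe_0902	probe_0940	probe_0950	probe_0994	probe_1021	probe_1051	probe_1110	probe_1139	probe_1152	probe_1190	probe_1199	probe_1216	probe_1285	probe_1456	probe_1551	probe_1605	probe_1618	probe_1656	probe_1723	probe_1754	probe_1809	probe_1842	probe_1874
CD8	synthetic CD8-lineage probe set (generated fixture, not biological annotation)	probe_0033	probe_0108	probe_0116	probe_0173	probe_0201	probe_0209	probe_0217	probe_0235	probe_0437	probe_0462	probe_0513	probe_0568	probe_0610	probe_0643	probe_0768	probe_0792	probe_0805	probe_0879	probe_0916	probe_1007	probe_1020	probe_1022	probe_1221	probe_1244	probe_1257	probe_1265	probe_1294	probe_1295	probe_1306	probe_1362	probe_1373	probe_1378	probe_1381	probe_1458	probe_1463	probe_1498	probe_1538	probe_1608	probe_1633	probe_1707	probe_1716	probe_1747	probe_1750	probe_1797	probe_1798	probe_1819	probe_1827	probe_1841	probe_1961	probe_1993
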