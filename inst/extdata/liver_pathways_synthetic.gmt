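lp01	Drug metabolism - cytochrome P450 (synthetic gene set)	gene_0025	gene_0044	gene_0063	gene_0199	gene_0293	gene_0300	gene_0381	gene_0413	gene_0435	gene_0459	gene_0487	gene_0517	gene_0615	gene_0630	gene_0708	gene_0746	gene_0748	gene_0897	gene_0919	gene_1005	gene_1006	gene_1076	gene_1222	gene_1390	gene_1430	gene_1469	gene_1505	gene_1527	gene_1604	gene_1619	gene_1622	gene_1698	gene_1735	gene_1774	gene_1799	gene_1805	gene_1894	gene_1966
lp02	Metabolism of xenobiotics by cytochrome P450 (synthetic gene set)	gene_0023	gene_0084	gene_0131	gene_0174	gene_0177	gene_0199	gene_0276	gene_0323	gene_0350	gene_0530	gene_0640	gene_0777	gene_0818	gene_0897	gene_1007	gene_1061	gene_1093	gene_1229	gene_1296	gene_1316	gene_1337	gene_1367	gene_1444	gene_1469	gene_1546	gene_1579	gene_1617	gene_1627	gene_1649	gene_1702	gene_1732	gene_1811	gene_1861	gene_1932	gene_1945	gene_1955
lp03	Primary bile acid biosynthesis (synthetic gene set)	gene_0056	gene_0090	gene_0131	gene_0162	gene_0196	gene_0241	gene_0398	gene_0511	gene_0598	gene_0680	gene_0766	gene_0812	gene_0947	gene_1058	gene_1079	gene_1210	gene_1329	gene_1390	gene_1412	gene_1526	gene_1597	gene_1728	gene_1788	gene_1832	gene_1841	gene_1882	gene_1906	gene_1985
lp04	Bile secretion (synthetic gene set)	gene_0111	gene_0131	gene_0152	gene_0249	gene_0296	gene_0348	gene_0390	gene_0406	gene_0844	gene_0845	gene_0863	gene_0900	gene_1040	gene_1076	gene_1104	gene_1187	gene_1230	gene_1231	gene_1502	gene_1656	gene_1842	gene_1960
lp05	Fatty acid degradation (synthetic gene set)	gene_0010	gene_0017	gene_0133	gene_0192	gene_0254	gene_0255	gene_0300	gene_0326	gene_0339	gene_0439	gene_0445	gene_0448	gene_0489	gene_0562	gene_0591	gene_0592	gene_0621	gene_0750	gene_0759	gene_0775	gene_0805	gene_0831	gene_0881	gene_0904	gene_0928	gene_0987	gene_0990	gene_1028	gene_1074	gene_1083	gene_1093	gene_1145	gene_1177	gene_1248	gene_1283	gene_1342	gene_1412	gene_1425	gene_1469	gene_1490	gene_1618	gene_1678	gene_1750	gene_1763	gene_1823	gene_1856	gene_1898	gene_1917	gene_1967	gene_1976
lp06	Fatty acid biosynthesis (synthetic gene set)	gene_0017	gene_0060	gene_0071	gene_0102	gene_0112	gene_0218	gene_0353	gene_0390	gene_0397	gene_0461	gene_0525	gene_0542	gene_0573	gene_0600	gene_0616	gene_0637	gene_0723	gene_0817	gene_0822	gene_0889	gene_1027	gene_1162	gene_1229	gene_1275	gene_1283	gene_1406	gene_1508	gene_1522	gene_1550	gene_1599	gene_1606	gene_1608	gene_1701	gene_1782	gene_1789	gene_1891	gene_1914	gene_1938
lp07	Steroid hormone biosynthesis (synthetic gene set)	gene_0111	gene_0229	gene_0254	gene_0289	gene_0457	gene_0521	gene_0614	gene_0620	gene_0759	gene_0888	gene_0919	gene_1218	gene_1274	gene_1327	gene_1405	gene_1668	gene_1776
lp08	Retinol metabolism (synthetic gene set)	gene_0153	gene_0246	gene_0304	gene_0312	gene_0546	gene_0588	gene_0770	gene_0855	gene_0944	gene_1010	gene_1233	gene_1321	gene_1349	gene_1360	gene_1429	gene_1699	gene_1981
lp09	Tryptophan metabolism (synthetic gene set)	gene_0009	gene_0125	gene_0141	gene_0152	gene_0245	gene_0248	gene_0282	gene_0293	gene_0499	gene_0524	gene_0552	gene_0613	gene_0657	gene_0667	gene_0708	gene_0817	gene_0821	gene_0835	gene_0836	gene_0897	gene_0905	gene_0949	gene_1000	gene_1085	gene_1093	gene_1209	gene_1306	gene_1359	gene_1435	gene_1451	gene_1461	gene_1492	gene_1559	gene_1601	gene_1696	gene_1708	gene_1745	gene_1778	gene_1799	gene_1919	gene_1927	gene_1942	gene_1951	gene_1965	gene_1989
lp10	Glycolysis / Gluconeogenesis (synthetic gene set)	gene_0002	gene_0054	gene_0419	gene_0579	gene_0720	gene_0730	gene_0756	gene_0890	gene_0929	gene_0945	gene_1084	gene_1106	gene_1173	gene_1391	gene_1423	gene_1488	gene_1730	gene_1805	gene_1994
lp11	PPAR signaling pathway (synthetic gene set)	gene_0020	gene_0116	gene_0194	gene_0199	gene_0271	gene_0297	gene_0356	gene_0370	gene_0492	gene_0554	gene_0626	gene_0692	gene_0719	gene_0723	gene_0761	gene_0790	gene_0846	gene_0953	gene_0995	gene_1216	gene_1316	gene_1337	gene_1456	gene_1469	gene_1478	gene_1560	gene_1574	gene_1657	gene_1676	gene_1696	gene_1811	gene_1840	gene_1848	gene_1852
lp12	Complement and coagulation cascades (synthetic gene set)	gene_0201	gene_0219	gene_0250	gene_0262	gene_0291	gene_0500	gene_0598	gene_0610	gene_0623	gene_0918	gene_1130	gene_1295	gene_1433	gene_1805	gene_1812	gene_1860
lp13	Base excision repair (synthetic gene set)	gene_0067	gene_0091	gene_0093	gene_0246	gene_0540	gene_0607	gene_0876	gene_1051	gene_1076	gene_1488	gene_1572	gene_1696	gene_1804	gene_1965
lp14	Nucleotide excision repair (synthetic gene set)	gene_0073	gene_0075	gene_0097	gene_0101	gene_0124	gene_0136	gene_0310	gene_0439	gene_0446	gene_0580	gene_0731	gene_0735	gene_0773	gene_0847	gene_0868	gene_0887	gene_0897	gene_0957	gene_0981	gene_1033	gene_1104	gene_1137	gene_1152	gene_1297	gene_1376	gene_1440	gene_1510	gene_1513	gene_1527	gene_1549	gene_1691	gene_1737	gene_1804	gene_1806	gene_1857	gene_1887	gene_1923
lp15	Mismatch repair (synthetic gene set)	gene_0266	gene_0278	gene_0356	gene_0453	gene_0496	gene_0540	gene_0553	gene_0558	gene_0610	gene_0621	gene_0628	gene_0717	gene_0756	gene_0846	gene_0853	gene_1067	gene_1156	gene_1161	gene_1170	gene_1259	gene_1289	gene_1299	gene_1391	gene_1415	gene_1465	gene_1529	gene_1587	gene_1715	gene_1772	gene_1777	gene_1846	gene_1915	gene_1966	gene_1992	gene_1998
lp16	Cell cycle (synthetic gene set)	gene_0040	gene_0071	gene_0164	gene_0183	gene_0198	gene_0265	gene_0296	gene_0336	gene_0343	gene_0381	gene_0436	gene_0445	gene_0459	gene_0501	gene_0511	gene_0526	gene_0592	gene_0697	gene_0763	gene_0820	gene_0854	gene_0856	gene_0869	gene_0936	gene_1002	gene_1006	gene_1071	gene_1073	gene_1094	gene_1110	gene_1143	gene_1145	gene_1162	gene_1234	gene_1362	gene_1367	gene_1385	gene_1390	gene_1408	gene_1528	gene_1556	gene_1557	gene_1617	gene_1623	gene_1700	gene_1818	gene_1830	gene_1855	gene_1910	gene_1957	gene_1977
lp17	Hepatitis B (synthetic gene set)	gene_0167	gene_0323	gene_0498	gene_0559	gene_0651	gene_0886	gene_0977	gene_1012	gene_1218	gene_1259	gene_1327	gene_1413	gene_1517	gene_1900	gene_1906	gene_1946
lp18	Pathways in cancer (synthetic gene set)	gene_0174	gene_0276	gene_0400	gene_0441	gene_0740	gene_1220	gene_1294	gene_1304	gene_1398	gene_1795	gene_1796	gene_1959	gene_1960
lp19	Chemical carcinogenesis (synthetic gene set)	gene_0011	gene_0119	gene_0130	gene_0231	gene_0359	gene_0421	gene_0452	gene_0473	gene_0554	gene_0575	gene_0638	gene_0659	gene_0684	gene_0689	gene_0720	gene_0773	gene_0820	gene_0985	gene_1016	gene_1024	gene_1034	gene_1063	gene_1097	gene_1145	gene_1148	gene_1167	gene_1219	gene_1244	gene_1259	gene_1276	gene_1335	gene_1369	gene_1432	gene_1434	gene_1469	gene_1480	gene_1536	gene_1547	gene_1559	gene_1577	gene_1592	gene_1653	gene_1694	gene_1727	gene_1739	gene_1791	gene_1802
lp20	Peroxisome (synthetic gene set)	gene_0064	gene_0087	gene_0161	gene_0179	gene_0231	gene_0241	gene_0385	gene_0396	gene_0406	gene_0428	gene_0488	gene_0651	gene_0768	gene_0834	gene_0891	gene_0923	gene_0941	gene_0955	gene_0970	gene_0989	gene_1018	gene_1037	gene_1050	gene_1067	gene_1116	gene_1191	gene_1218	gene_1236	gene_1257	gene_1258	gene_1266	gene_1338	gene_1341	gene_1411	gene_1477	gene_1506	gene_1536	gene_1613	gene_1793	gene_1806	gene_1813	gene_1878	gene_1895	gene_1919	gene_1946	gene_1984	gene_1994
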