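gene	annotation_id	genbank_accession	orf_length	gene_length	est_hits	expressed	cds_obtained
CsWRKY1	Csa005379	NA	1773	3659	NA	-	NA
CsWRKY2	Csa004516	NA	1731	2527	4	+	NA
CsWRKY3	Csa003764	NA	1839	3302	NA	-	NA
CsWRKY4	Csa016371	GU984009	1521	3200	6	+	+
CsWRKY5	Csa015868	GU984010	828	1150	2	+	+
CsWRKY6	Csa017345	GU984011	858	1027	NA	+	+
CsWRKY7	Csa001650	NA	804	2800	1	+	NA
CsWRKY8	Csa006570	NA	2184	10512	1	+	NA
CsWRKY9	Csa026380	GU984012	1047	1704	NA	+	+
CsWRKY10	Csa014665	NA	NA	NA	NA	NA	NA
CsWRKY11	Csa005866	NA	768	1648	NA	-	NA
CsWRKY12	Csa005867	GU984014	540	953	1	+	+
CsWRKY13	Csa005948	NA	399	630	NA	+	NA
CsWRKY14	Csa001212	GU984015	882	1364	1	+	+
CsWRKY15	Csa018420	GU984016	681	758	2	+	+
CsWRKY16	Csa018419	NA	1506	2683	NA	NA	NA
CsWRKY17	Csa020112	GU984017	1581	6663	1	+	+
CsWRKY18	Csa000336	GU984018	1005	1202	1	+	+
CsWRKY19	Csa008740	GU984019	1239	2839	1	+	+
CsWRKY20	Csa019944	NA	849	1123	NA	+	NA
CsWRKY21	Csa004863	GU984020	948	1321	2	+	+
CsWRKY22	Csa004896	GU984021	843	962	2	+	+
CsWRKY23	Csa004828	GU984022	1431	2653	1	+	+
CsWRKY24	Csa004742	GU984023	1473	2219	1	+	+
CsWRKY25	Csa002274	GU984024	939	1614	1	+	+
CsWRKY26	Csa002896	GU984025	645	1198	NA	+	+
CsWRKY27	Csa002813	NA	873	1123	NA	+	NA
CsWRKY28	Csa016219	NA	315	1475	NA	+	NA
CsWRKY29	Csa016218	NA	810	1328	NA	-	NA
CsWRKY30	Csa010443	NA	840	2017	NA	-	NA
CsWRKY31	Csa020355	NA	1068	1737	NA	+	NA
CsWRKY32	Csa014848	GU984026	975	2909	1	+	+
CsWRKY33	Csa009473	GU984027	1152	1559	1	+	+
CsWRKY34	Csa016087	GU984028	822	2410	NA	+	+
CsWRKY35	Csa016061	NA	954	5996	NA	+	NA
CsWRKY36	Csa015442	NA	918	1432	NA	+	NA
CsWRKY37	Csa009672	GU984029	1521	4068	2	+	+
CsWRKY38	Csa019857	GU984030	732	3117	NA	+	+
CsWRKY39	Csa019858	NA	453	592	NA	+	NA
CsWRKY40	Csa019119	NA	522	522	NA	+	NA
CsWRKY41	Csa013101	NA	510	3539	NA	+	NA
CsWRKY42	Csa013154	NA	618	2623	NA	+	NA
CsWRKY43	Csa010294	GU984031	546	2318	1	+	+
CsWRKY44	Csa010089	NA	432	2005	NA	+	NA
CsWRKY45	Csa010221	NA	885	1063	NA	-	NA
CsWRKY46	Csa000701	GU984032	786	1754	3	+	+
CsWRKY47	Csa003388	GU984033	897	2148	1	+	+
CsWRKY48	Csa013553	NA	1449	2980	NA	-	NA
CsWRKY49	Csa013650	GU984034	1302	1983	1	+	+
CsWRKY50	Csa007193	GU984035	876	1554	1	+	+
CsWRKY51	Csa016725	GU984036	1056	1726	1	+	+
CsWRKY52	Csa001863	GU984037	729	2911	NA	+	+
CsWRKY53	Csa018657	GU984038	741	2095	1	+	+
CsWRKY54	Csa018622	GU984039	240	1886	NA	+	+
CsWRKY55	Csa018069	GU984040	807	2807	1	+	+
CsWRKY56	Csa018094	GU984041	498	2565	NA	+	+
CsWRKY57	Csa022995	NA	972	1454	NA	+	NA
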