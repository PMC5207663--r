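region	chrom	start	end	n_amplicons	targeted_bases	covered_bases	fraction_covered
GRMZM2G154580	chr1	90221947	90224841	12	2894	2894	1
GRMZM2G011357	chr1	239667869	239673192	25	5323	5283	0.992
GRMZM2G180190	chr2	12649206	12654213	19	5007	4520	0.903
GRMZM2G095598	chr2	33216134	33219640	11	3506	2600	0.742
GRMZM2G033962	chr2	219433832	219441286	30	7454	6506	0.873
GRMZM2G031432	chr3	3986806	3988589	6	1783	1358	0.762
GRMZM2G031432	chr3	3990583	3990969	2	386	386	1
GRMZM2G031432	chr3	3994128	3996072	8	1944	1944	1
GRMZM2G031432	chr3	4139301	4140050	3	749	749	1
GRMZM2G045275	chr3	218979525	218987381	29	7856	6644	0.846
GRMZM2G067921	chr7	175583965	175587451	10	3486	2488	0.714
GRMZM2G179264	chr8	123030387	123034175	16	3788	3554	0.938
vgt1	chr8	131517263	131519147	10	1884	1868	0.992
GRMZM2G700665	chr8	131574889	131580316	16	5427	3902	0.719
GRMZM2G405368	chr9	35633308	35639846	23	6538	5354	0.819
GRMZM2G085218	chr9	106530026	106533123	11	3097	2641	0.853
GRMZM2G038783	chr9	108445974	108449794	13	3820	2964	0.776
GRMZM2G359322	chr9	123215070	123218079	9	3009	2012	0.669
GRMZM2G092174	chr9	135245567	135253882	34	8315	7302	0.878
GRMZM2G381691	chr10	94262291	94272461	32	10170	7228	0.711
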