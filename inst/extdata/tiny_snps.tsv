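chr1	50	51	rs1001	single	by-cluster,by-1000genomes
chr1	299	300	rs1002	single	by-1000genomes
chr1	300	301	rs1003	single	by-1000genomes
chr1	9400	9401	rs1004	single	by-1000genomes
chr1	9600	9601	rs1005	single	by-1000genomes
chr1	9800	9801	rs1006	single	by-1000genomes
chr1	9800	9801	rs1006	single	by-1000genomes
chr1	9850	9853	rs1007	deletion	by-1000genomes
chr1	9860	9861	rs1008	single	by-frequency,by-cluster
chr1	9999	10000	rs1009	single	by-1000genomes
chr1	10000	10001	rs1010	single	by-1000genomes
chr1	10100	10101	rs1011	single	by-1000genomes
chr1	21900	21901	rs1012	single	by-1000genomes
chr1	22000	22001	rs1013	single	By-1000Genomes
chr1	22400	22401	rs1014	single	by-1000genomes
chr1	22900	22901	rs1015	single	by-1000genomes
chr1	29550	29551	rs1016	single	by-1000genomes
chr1	29700	29701	rs1017	single	by-1000genomes
chr2	10	11	rs2001	single	by-1000genomes
chr2	49100	49101	rs2002	single	by-1000genomes
chr2	49900	49901	rs2003	single	by_1000genomes
chr2	50050	50051	rs2004	single	by-1000genomes
chr2	63700	63701	rs2005	single	by-1000genomes
chr2	64100	64101	rs2006	single	by-1000genomes
chr2	69400	69401	rs2007	single	by-1000genomes
chr2	69600	69601	rs2008	single	by-1000genomes
chr2	69600	69601	rs2009	single	by-1000genomes
chr2	81200	81201	rs2010	single	by-1000genomes
chr2	82100	82101	rs2011	single	by-1000genomes
chr2	91700	91701	rs2012	single	by-1000genomes
chr2	92300	92301	rs2013	single	by-1000genomes
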