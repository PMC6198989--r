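gene_id	chrom	strand	tss
G0014	chr1	-	86129
G0007	chr1	-	87514
G0018	chr1	-	170321
G0006	chr1	+	188369
G0016	chr1	+	190071
G0003	chr1	-	207930
G0011	chr1	-	212577
G0012	chr1	+	260877
G0013	chr1	-	263072
G0015	chr1	-	280193
G0001	chr1	-	377695
G0019	chr1	+	474467
G0005	chr2	-	49097
G0009	chr2	+	160705
G0004	chr2	+	166768
G0008	chr2	+	211025
G0002	chr2	-	276256
G0010	chr2	-	341157
G0017	chr2	+	370504
G0020	chr2	+	400963
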