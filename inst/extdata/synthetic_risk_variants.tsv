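variant_id	chrom	pos	risk_allele	other_allele	beta	p
rs0638346	chr15	67320929	A	G	0.098803255180366	9.13397963514195e-12
rs2003314	chr15	67423432	C	G	0.0948438902075976	2.44980548852029e-12
rs8758910	chr15	67553946	G	A	0.130207702416788	5.65578731786987e-12
rs8777064	chr15	67559332	C	A	0.0958452983671569	9.11007189735855e-12
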