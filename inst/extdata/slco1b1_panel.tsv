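# Default SLCO1B1 site panel (GRCh38, gene window chr12:21131194-21239796).
# Common star-allele sites plus rare missense sites used in the rare-variant
# scan. Positions of rare sites and of the *45/*46 placeholder sites are
# approximate/synthetic; consequence and impact stand in for VEP output.
rsid	chrom	pos	ref	alt	consequence	impact
rs373327528	chr12	21176661	G	A	missense_variant	MODERATE
rs2306283	chr12	21176804	A	G	missense_variant	MODERATE
rs11045819	chr12	21176868	C	A	missense_variant	MODERATE
rs4149056	chr12	21178615	T	C	missense_variant	MODERATE
rs000045	chr12	21190000	G	A	missense_variant	MODERATE
rs000046	chr12	21191000	C	T	missense_variant	MODERATE
rs374113543	chr12	21196700	G	A	missense_variant	MODERATE
rs960742177	chr12	21200000	C	T	missense_variant	MODERATE
rs780911188	chr12	21205000	G	C	missense_variant	MODERATE
rs34671512	chr12	21239042	A	C	missense_variant	MODERATE
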