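# SLCO1B1 star-allele definition table.
# role "defining": the allele is a single-variant star allele and copies equal
#   the dosage of risk_allele at rsid.
# role "constituent": the allele is a multi-variant haplotype; an (unphased)
#   carrier holds >= 1 risk allele at EVERY constituent site.
# The *45/*46 rows are synthetic placeholders (the defining sites of these
# rare alleles are nomenclature-dependent); replace with a current definition
# table as needed.
star_allele	rsid	risk_allele	role
*5	rs4149056	C	defining
*37	rs2306283	G	defining
*4	rs11045819	A	defining
*19	rs34671512	C	defining
*45	rs000045	A	defining
*46	rs000046	T	defining
*15	rs4149056	C	constituent
*15	rs2306283	G	constituent
*14	rs11045819	A	constituent
*14	rs2306283	G	constituent
*20	rs2306283	G	constituent
*20	rs34671512	C	constituent
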