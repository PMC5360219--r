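# SYNTHETIC effect-allele frequencies for the 31 PHS SNPs.
# These are NOT the 1000 Genomes European frequencies used to build the
# published reference distribution; they are a deterministic stand-in panel
# (common-variant range) so the reference-distribution and calibration
# machinery can be exercised without external downloads.
snp	effect_allele	freq
rs4266886	A	0.27
rs61822977	A	0.34
rs6733839	T	0.41
rs10202748	A	0.22
rs115124923	A	0.12
rs115675626	A	0.18
rs1109581	T	0.45
rs17265593	C	0.15
rs2597283	C	0.19
rs1476679	C	0.29
rs78571833	A	0.11
rs12679874	C	0.37
rs2741342	T	0.33
rs7831810	A	0.36
rs1532277	T	0.32
rs9331888	C	0.28
rs7920721	G	0.39
rs3740688	G	0.40
rs7116190	A	0.42
rs526904	T	0.35
rs543293	A	0.31
rs11218343	C	0.04
rs6572869	A	0.26
rs12590273	C	0.21
rs7145100	A	0.44
rs74615166	C	0.05
rs2526378	A	0.43
rs117481827	T	0.08
rs7408475	A	0.16
rs3752246	G	0.19
rs7274581	C	0.09
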