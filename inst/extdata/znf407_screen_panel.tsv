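site_id	kind	aa_change	maf	carriers	panel_size
rs75994611	SNP	Ser61Gly	0.0115	4	52
rs3794942	SNP	Asn69Ser	0.0744	4	52
rs200158544	SNP	Val143Phe	?	1	52
novel_A898C	novel	Asn300His	?	1	52
rs115368653	SNP	Glu343Lys	0.0078	1	52
rs77148611	SNP	Val359	0.0096	2	52
rs3794941	SNP	Pro416	0.2020	16	52
rs17817969	SNP	Leu421	0.079	12	52
rs191767705	SNP	Arg507	0.0032	1	52
rs77006793	SNP	Pro508Leu	0.0032	1	52
rs7227263	SNP	Gly512Arg	0.079	11	52
rs7227391	SNP	Thr526	0.0794	12	52
rs139800364	SNP	Leu643	0.0014	1	52
rs374273356	SNP	Lys725Thr	?	1	52
rs201078153	SNP	Val956Ile	?	1	52
rs948615	SNP	Asn972Thr	0.2025	10	52
rs73971116	SNP	Leu1020Trp	0.0023	1	52
rs368982407	SNP	Arg1038Trp	?	1	52
rs12327359	SNP	Leu1503	0.4096	35	52
rs114095914	SNP	Thr1524	0.0078	1	52
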