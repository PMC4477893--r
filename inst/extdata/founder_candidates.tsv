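gene	consequence	variant_class	alt_count	coverage	dbsnp_id
KIT	nonsynonymous SNV	SNV	14	53	rs121913517
PCDHB11	nonsynonymous SNV	SNV	12	32
RNF146	frameshift del	deletion	24	52
OPLAH	nonsynonymous SNV	SNV	10	29	rs200933200
TESK1	nonsynonymous SNV	SNV	11	28
MYRF	nonsynonymous SNV	SNV	10	32
SLC39A9	nonsynonymous SNV	SNV	24	37
RRN3P1	noncoding variant	SNV	8	37
ZNF407	nonsynonymous SNV	SNV	17	53	rs368982407
LAMA5	nonsynonymous SNV	SNV	10	34
DOPEY2	nonsynonymous SNV	SNV	20	59
STS	nonsynonymous SNV	SNV	21	25	rs373509256
MAGEB16	nonsynonymous SNV	SNV	24	28
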