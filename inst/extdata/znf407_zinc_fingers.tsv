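motif_id	aa_start	aa_end	motif_seq	variant	dbsnp_id	offset_in_motif
zf_705	705	728	CkkCfyktrsstvltrHiklrH	Lys725Thr	rs374273356	19
zf_1017	1017	1040	ClhCefsahssaslelHvkrkH	Leu1020Trp	rs73971116	2
zf_1017	1017	1040	ClhCefsahssaslelHvkrkH	Arg1038Trp	rs368982407	20
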