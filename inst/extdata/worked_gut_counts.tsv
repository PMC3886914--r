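contig_id	length	GUT	WB
RP-3602	1000	7966	619
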