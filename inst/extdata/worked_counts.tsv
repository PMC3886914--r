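contig_id	length	WB	AM	PM	RE
RP-2217	1000	72	1113	609	1135
RP-2259	1000	64	1	504	2346
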