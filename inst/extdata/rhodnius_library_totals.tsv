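library_id	total_reads
WB	862980
AM	156780
PM	145986
RE	170565
FB	177944
MT	186149
OV	111190
TE	140156
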