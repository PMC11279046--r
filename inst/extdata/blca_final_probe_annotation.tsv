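probe_id	gene	chromosome	position
cg11304234	IL18	chr11	112013974
cg16269144	PRKCZ	chr1	2050411
cg16624272	PTK2	chr8	141668439
cg26534425	IL18	chr11	112017652
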