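term_id	term_name	count	p_value	genes
GO:0010744	positive regulation of macrophage-derived foam cell differentiation	3	0.002	PRKCH;IL18;NFKB1
GO:0031032	actomyosin structure organization	3	0.004	EPB41L1;CDC42BPG;MYO18A
GO:0030010	establishment of cell polarity	3	0.006	PRKCZ;PTK2;MARK2
GO:0030036	actin cytoskeleton organization	5	0.006	CAPZB;PTK7;CDC42BPG;FHL3;ANTXR1
GO:0035556	intracellular signal transduction	6	0.013	PRKCH;ASB13;TGFA;PRKCZ;MARK2;MAP4K4
GO:0030155	regulation of cell adhesion	3	0.017	IL18;CYTH1;PTK2
GO:0060463	lung lobe morphogenesis	2	0.023	LIF;GRHL2
GO:0045630	positive regulation of T-helper 2 cell differentiation	2	0.023	IL18;PRKCZ
GO:0008284	positive regulation of cell proliferation	6	0.026	LIF;GCNT2;TGFA;PRKCZ;PTK2;TRPM4
GO:0043066	negative regulation of apoptotic process	6	0.026	MYO18A;PRKCZ;PTK2;NFKB1;LIMS2;MAP4K4
GO:0090179	planar cell polarity pathway involved in neural tube closure	2	0.036	PTK7;GRHL3
GO:0007179	transforming growth factor beta receptor signaling pathway	3	0.044	ZMIZ1;GCNT2;PTK2
GO:0016477	cell migration	4	0.046	PTK7;MYO18A;PRKCZ;PTK2
GO:0032736	positive regulation of interleukin-13 production	2	0.049	IL18;PRKCZ
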