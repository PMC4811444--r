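sample_id	gene	hgvs_c	hgvs_p	tumour_vaf	normal_vaf	published_type	published_origin
3506	BRCA1	c.5329dupC	p.Gln1777ProfsTer74	0.91	0.50	frameshift	germline
3513	BRCA1	c.676delT	p.Cys226ValfsTer8	0.90	0.49	frameshift	germline
3508	BRCA1	c.1687C>T	p.Gln563Ter	0.47	0.51	nonsense	germline
3521	BRCA1	c.2405_2406delTG	p.Val802GlufsTer7	0.49	0.48	frameshift	germline
3528	BRCA1	c.2405_2406delTG	p.Val802GlufsTer7	0.46	0.50	frameshift	germline
3489	BRCA1	c.3767_3768delCA	p.Thr1256ArgfsTer10	0.52	0.47	frameshift	germline
3505	BRCA1	c.5125_5127delGTT	p.Val1709del	0.48	0.52	inframe_deletion	germline
3520	BRCA1	c.5309C>T	p.Pro1770Leu	0.45	0.49	missense	germline
3512	BRCA2	c.2813delC	p.Ala938GlufsTer22	0.38	0.00	frameshift	somatic
3523	BRCA2	c.6202dupA	p.Ile2068AsnfsTer10	0.92	0.51	frameshift	germline
3514	BRCA2	c.6574delA	p.Met2192TrpfsTer14	0.50	0.48	frameshift	germline
3501	BRCA2	c.7069_7070delCT	p.Leu2357ValfsTer2	0.36	0.01	frameshift	somatic
3516	BRCA2	c.8614G>T	p.Glu2872Ter	0.41	0.00	nonsense	somatic
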