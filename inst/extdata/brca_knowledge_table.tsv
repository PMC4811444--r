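gene	hgvs_c	hgvs_p	sig_germline	sig_somatic	population_af
BRCA1	c.5329dupC	p.Gln1777ProfsTer74	Pathogenic	NA	NA
BRCA1	c.676delT	p.Cys226ValfsTer8	Pathogenic	NA	NA
BRCA1	c.1687C>T	p.Gln563Ter	Pathogenic	NA	NA
BRCA1	c.2405_2406delTG	p.Val802GlufsTer7	Pathogenic	NA	NA
BRCA1	c.3767_3768delCA	p.Thr1256ArgfsTer10	Pathogenic	NA	NA
BRCA1	c.5125_5127delGTT	p.Val1709del	Pathogenic	NA	NA
BRCA1	c.5309C>G	p.Pro1770Arg	Pathogenic	NA	NA
BRCA2	c.6202dupA	p.Ile2068AsnfsTer10	Pathogenic	NA	NA
BRCA2	c.7069_7070delCT	p.Leu2357ValfsTer2	Pathogenic	NA	NA
BRCA1	c.3119G>A	p.Ser1040Asn	Benign|Benign|Benign|Benign|Benign|Likely_benign|Likely_benign|Likely_benign|Uncertain_significance|Pathogenic	NA	0.01
BRCA2	c.1114A>C	p.Asn372His	Benign|Benign|Benign|Benign|Pathogenic	NA	0.25
BRCA2	c.865A>C	p.Asn289His	Benign|Benign|Benign|Benign|Benign|Benign|Benign	NA	0.07
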