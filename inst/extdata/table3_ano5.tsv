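# Heterozygous ANO5 variants of the five-patient limb-girdle muscular dystrophy
# cohort (one row per distinct variant; Asp81Gly was carried by two patients).
# maf = ExAC frequency ("0" = not observed). Predictor columns hold the
# published PolyPhen2/SIFT verdicts; mutation_taster and provean verdicts were
# not printed per-variant and are left absent. The dbscSNV ada/rf scores for
# His841Asp are SYNTHETIC placeholders: only "both scores > 0.6" was reported.
gene	cdna	protein	type	location	maf	polyphen2	sift	mutation_taster	provean	ada_score	rf_score	acmg
ANO5	c.69C>A	p.Tyr23Ter	nonsense	11:22203832	9.84e-06	stop gained	deleterious					PVS1;PM2;PM3;PP4
ANO5	c.191dupA	p.Asn64LysfsTer15	frameshift	11:22221107	1.03e-03	frameshift	deleterious					PVS1;PM3;PP4;PP5
ANO5	c.242A>G	p.Asp81Gly	missense	11:22221158	2.25e-04	probably damaging	deleterious					PS4;PM3;PP3;PP4;PP5
ANO5	c.395A>T	p.Lys132Met	missense	11:22227333	0	probably damaging	deleterious					PM2;PM3;PP3;PP4
ANO5	c.1203G>A	p.Trp401Ter	nonsense	11:22255393	0	stop gained	deleterious					PVS1;PM2;PM3;PP3;PP4
ANO5	c.1664G>T	p.Ser555Ile	missense	11:22262162	7.42e-05	possibly damaging	deleterious					PM3;PP3;PP4
ANO5	c.2012A>G	p.Tyr671Cys	missense	11:22270425	8.24e-06	probably damaging	deleterious					PM2;PM3;PP3;PP4
ANO5	c.2272C>T	p.Arg758Cys	missense	11:22274605	3.30e-05	probably damaging	deleterious					PS4;PM3;PP3;PP4;PP5
ANO5	c.2521C>G	p.His841Asp	missense	11:22279544	1.67e-05	probably damaging	deleterious			0.75	0.71	PM2;PM3;PP3;PP5;PP4
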