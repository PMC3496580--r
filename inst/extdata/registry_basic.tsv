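Input	Output	Tool	Language	Code	XI	XO	Performance	Observations	Provider	Contact
PolyPhred	PrettyBase	PolyPhred2PrettyBase.pl	perl	1	-	-	0.004	genotype section only	LDGH	ldgh@example.org
PrettyBase	SDAT	PrettyBase2SDAT.pl	perl	2	-	-	0.01		LDGH	ldgh@example.org
SDAT	StructureFormat	SDAT2Structure.pl	perl	5	-	mainparam,extraparam	0.15	writes Structure parameter files	LDGH	ldgh@example.org
SDAT	RHierfstat	SDAT2Rhierfstat.pl	perl	7	SDAT	-	0.02	one SDAT file per population	LDGH	ldgh@example.org
PHASEOUT	Fasta	Phase2Fasta.pl	perl	9	Fragments,RefSeq	-	0.02	needs site map and reference	LDGH	ldgh@example.org
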