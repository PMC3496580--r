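Input	Output	Tool	Language	Code	XI	XO	Performance	Observations	Provider	Contact
PolyPhred	PrettyBase	PolyPhred2PrettyBase.pl	perl	1	-	-	0.004	genotype section only	LDGH	ldgh@example.org
PrettyBase	SDAT	PrettyBase2SDAT.pl	perl	2	-	-	0.01		LDGH	ldgh@example.org
PrettyBase	SDAT	PrettyBase2SDATv2.pl	perl	3	-	-	0.05	rewritten version, kept as alternative	LDGH	ldgh@example.org
SDAT	PrettyBase	SDAT2PrettyBase.pl	perl	4	-	-	0.012		LDGH	ldgh@example.org
SDAT	StructureFormat	SDAT2Structure.pl	perl	5	-	mainparam,extraparam	0.15	writes Structure parameter files	LDGH	ldgh@example.org
SDAT	RGenetics	SDAT2Rgenetics.pl	perl	6	SDAT	-	0.05	one SDAT file per population	LDGH	ldgh@example.org
SDAT	RHierfstat	SDAT2Rhierfstat.pl	perl	7	SDAT	-	0.02	one SDAT file per population	LDGH	ldgh@example.org
SDAT	PHASEIN	SDAT2Phase.pl	perl	8	-	-	0.03		LDGH	ldgh@example.org
PHASEOUT	Fasta	Phase2Fasta.pl	perl	9	Fragments,RefSeq	-	0.02	needs site map and reference	LDGH	ldgh@example.org
SDAT	NEXUS	SDAT2NEXUS.pl	perl	10	-	-	0.21		LDGH	ldgh@example.org
NEXUS	RHierfstat	NEXUS2Rhierfstat.pl	perl	11	NEXUS	-	0.15	one NEXUS file per population	LDGH	ldgh@example.org
Fasta	NEXUS	Fasta2NEXUS.pl	perl	12	-	-	0.08		LDGH	ldgh@example.org
PHASEOUT	Haploview	Phase2Haploview.pl	perl	13	-	-	0.04	phased linkage input	LDGH	ldgh@example.org
PHASEOUT	NEXUS	Phase2NEXUS.pl	perl	14	-	-	0.12		LDGH	ldgh@example.org
PrettyBase	PHASEIN	PrettyBase2Phase.pl	perl	15	-	-	0.02		LDGH	ldgh@example.org
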