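antigen	accession	diseases	human	ln	identity	similarity	mtg
Fibrinogen alpha chain	P02671	AIAS;AS;RA;PA	PSRGKSSSYSKQF	13	8	9	PSRMKAVIYSKHF
Histone H1.2	P16403	AIT;SS	SETAPAAPAAAP	12	7	10	NESAPAASSAGP
Dihydrolipoyllysine-residue acetyltransferase component of pyruvate dehydrogenase complex, mitochondrial	P10515	PBC;SS;T1DM	AATASPPTPSAQAP	14	7	8	APAASSAGPSFRAP
Creatine kinase S-type, mitochondrial	P17540	RA;T1DM	REVENVAITALE	12	7	8	REVASVMNRALE
Dimethyladenosine transferase 2, mitochondrial	Q9H5Q4	MS;RA	LKVVGMFPSRGEKRA	15	7	7	LCTAGFMPSAGEAAA
Cytochrome c1, heme protein, mitochondrial	P08574	AU;RA;T1DM	AANNGALPPDLSY	13	8	8	AADNGAGEETKSY
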