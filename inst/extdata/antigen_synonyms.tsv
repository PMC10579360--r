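alias	canonical
fibrinogen alpha chain	fibrinogen
fibrinogen beta chain	fibrinogen
histone h1.2	histone
histone h1	histone
dihydrolipoyllysine-residue acetyltransferase component of pyruvate dehydrogenase complex, mitochondrial	mitochondrial m2
dlst	mitochondrial m2
pdc-e2	mitochondrial m2
m2	mitochondrial m2
mitochondria (m2)	mitochondrial m2
creatine kinase s-type, mitochondrial	mtck
dimethyladenosine transferase 2, mitochondrial	trmt10c
cytochrome c1, heme protein, mitochondrial	cytochrome c1
transglutaminase 2	tg2
tissue transglutaminase	tg2
transglutaminase 3	tg3
transglutaminase 6	tg6
extractable nuclear antigens	ena
anti-nuclear antigen	ana
antinuclear antigen	ana
thyroid peroxidase	tpo
dipeptidyl peptidase iv	dpp iv
growth hormone	somatotropin
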