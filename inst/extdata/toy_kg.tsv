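# miniature UMLS-style knowledge graph for the worked examples
aniridia	SY	gillespie syndrome 2	T047	T047
aniridia	SY	aniridia and absent patella syndrome	T047	T047
aniridia	PAR	congenital anterior segment disorders	T047	T047
aniridia	CHD	aniridia of left eye	T047	T047
alkaptonuria	SY	alkaptonuric ochronosis	T047	T047
alkaptonuria	SY	fetal diseases	T047	T047
alkaptonuria	SY	abnormal urine	T047	T047
alkaptonuria	SY	autosomal recessive hereditary disorder	T047	T047
myalgias	SY	neuromuscular pain	T184	T184
hypertension	SY	hypertensive disease	T047	T047
hypertension	PAR	vascular diseases	T047	T047
intracellular	SY	intracellular space	T082	T082
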