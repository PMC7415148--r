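kind	stem	carbons	double_bonds
suffix	anoic	NA	0
suffix	enoic	NA	1
suffix	dienoic	NA	2
suffix	trienoic	NA	3
suffix	tetraenoic	NA	4
suffix	pentaenoic	NA	5
suffix	hexaenoic	NA	6
root	etha	2	NA
root	propa	3	NA
root	buta	4	NA
root	penta	5	NA
root	hexa	6	NA
root	hepta	7	NA
root	octa	8	NA
root	nona	9	NA
root	deca	10	NA
root	undeca	11	NA
root	dodeca	12	NA
root	trideca	13	NA
root	tetradeca	14	NA
root	pentadeca	15	NA
root	hexadeca	16	NA
root	heptadeca	17	NA
root	octadeca	18	NA
root	nonadeca	19	NA
root	eicosa	20	NA
root	icosa	20	NA
root	heneicosa	21	NA
root	henicosa	21	NA
root	docosa	22	NA
root	tricosa	23	NA
root	tetracosa	24	NA
root	pentacosa	25	NA
root	hexacosa	26	NA
root	heptacosa	27	NA
root	octacosa	28	NA
root	nonacosa	29	NA
root	triaconta	30	NA
trivial	acetic	2	0
trivial	propionic	3	0
trivial	butyric	4	0
trivial	valeric	5	0
trivial	caproic	6	0
trivial	enanthic	7	0
trivial	caprylic	8	0
trivial	pelargonic	9	0
trivial	capric	10	0
trivial	lauric	12	0
trivial	myristic	14	0
trivial	myristoleic	14	1
trivial	pentadecylic	15	0
trivial	palmitic	16	0
trivial	palmitoleic	16	1
trivial	sapienic	16	1
trivial	margaric	17	0
trivial	stearic	18	0
trivial	oleic	18	1
trivial	elaidic	18	1
trivial	vaccenic	18	1
trivial	petroselinic	18	1
trivial	linoleic	18	2
trivial	linolelaidic	18	2
trivial	linolenic	18	3
trivial	stearidonic	18	4
trivial	nonadecylic	19	0
trivial	arachidic	20	0
trivial	gadoleic	20	1
trivial	gondoic	20	1
trivial	mead	20	3
trivial	arachidonic	20	4
trivial	timnodonic	20	5
trivial	behenic	22	0
trivial	erucic	22	1
trivial	brassidic	22	1
trivial	adrenic	22	4
trivial	clupanodonic	22	5
trivial	cervonic	22	6
trivial	lignoceric	24	0
trivial	nervonic	24	1
trivial	cerotic	26	0
trivial	montanic	28	0
trivial	melissic	30	0
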