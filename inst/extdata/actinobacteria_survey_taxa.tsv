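order	suborder	n_sequenced	n_with_pks
Acidimicrobiales	Acidimicrobineae	1	0
Actinomycetales	Actinomycineae	4	0
Actinomycetales	Catenulisporineae	1	1
Actinomycetales	Corynebacterineae	129	0
Actinomycetales	Frankineae	11	6
Actinomycetales	Glycomycineae	1	0
Actinomycetales	Kineosporiineae	3	0
Actinomycetales	Micrococcineae	48	1
Actinomycetales	Micromonosporineae	7	5
Actinomycetales	Propionibacterineae	12	0
Actinomycetales	Pseudonocardineae	11	2
Actinomycetales	Streptomycineae	36	6
Actinomycetales	Streptosporangineae	7	4
Bifidobacteriales	Bifidobacteriaceae	40	0
Coriobacteriales	Coriobacterineae	6	0
Rubrobacterales	Rubrobacterineae	1	0
Solirubrobacterales	Conexibacteraceae	1	0
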