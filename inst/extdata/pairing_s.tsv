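codon3	anticodon1	class	s
U	A	watson_crick	0
U	G	wobble	0.41
C	G	watson_crick	0
C	A	wobble	0.28
A	U	watson_crick	0
A	A	wobble	0.9999
G	C	watson_crick	0
G	U	wobble	0.68
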