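type	gene
CM	Ly6c2
CM	Ccr2
CM	Chil3
CM	Plac8
NCM	Ace
NCM	Ear2
NCM	Treml4
NCM	Itgal
cDC2	Cd209a
cDC2	Clec10a
cDC2	Sirpa
cDC2	Itgax
mcDC2	Ccr7
mcDC2	Fscn1
mcDC2	Ccl22
mcDC2	Cacnb3
Neutrophil	S100a8
Neutrophil	S100a9
Neutrophil	Retnlg
Neutrophil	Ngp
NK	Ncr1
NK	Nkg7
NK	Gzma
NK	Klrb1c
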