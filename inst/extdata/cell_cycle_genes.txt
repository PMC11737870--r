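Mki67
Top2a
Ccnb1
Ccnb2
Ccna2
Ccne1
Cdk1
Cdc20
Ube2c
Birc5
Pcna
Mcm2
Mcm3
Mcm5
Plk1
Aurka
Aurkb
Bub1
Tyms
Rrm2
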