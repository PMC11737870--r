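IFNG_RESPONSE	na	Stat1	Irf1	Gbp2	Gbp3	Gbp4	Gbp5	Cxcl9	Cxcl10	Irg1	Ly6a	Ifit1	Ifit3	Ifitm3	Socs3	Tap1	Psmb8	Psmb9	Igtp	Iigp1	Isg15
IFNA_RESPONSE	na	Isg15	Usp18	Rsad2	Oasl2	Ifit1	Ifit3	Ifitm3	Irf7	Bst2	Zbp1
IL6_JAK_STAT3	na	Socs3	Stat3	Il6ra	Osmr	Junb	Myc	Pim1	Cebpd
HEME_METABOLISM	na	Hmox1	Slc40a1	Spic	Blvrb	Alas2	Fech	Slc48a1	Abcb6
E2F_TARGETS	na	E2f1	Pcna	Mcm2	Mcm3	Mcm5	Tyms	Rrm2	Ccne1
G2M_CHECKPOINT	na	Mki67	Top2a	Ccnb1	Ccnb2	Cdk1	Bub1	Plk1	Aurka
COMPLEMENT	na	C1qa	C1qb	C1qc	C3	C4b	Cfb	Cfh	Itgam
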