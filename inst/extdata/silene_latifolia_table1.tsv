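name	anticodon	amino_acid	chloroplast_origin	pseudogene	initiator	lysidine
trnY(gua)	GUA	Tyr	FALSE	FALSE	FALSE	FALSE
trnC(gca)	GCA	Cys	FALSE	FALSE	FALSE	FALSE
trnP(ugg)	UGG	Pro	FALSE	FALSE	FALSE	FALSE
trnE(uuc)	UUC	Glu	FALSE	FALSE	FALSE	FALSE
trnI(cau)	CAU	Ile	FALSE	FALSE	FALSE	TRUE
trnfM(cau)	CAU	Met	FALSE	FALSE	TRUE	FALSE
trnW(cca)-cp	CCA	Trp	TRUE	FALSE	FALSE	FALSE
trnH(gug)-cp	GUG	His	TRUE	FALSE	FALSE	FALSE
trnN(guu)-cp	GUU	Asn	TRUE	FALSE	FALSE	FALSE
trnP-cp	UGG	Pro	TRUE	TRUE	FALSE	FALSE
trnM-cp(cau)	CAU	Met	TRUE	TRUE	FALSE	FALSE
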