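synonym	canonical
CO1	CO1
COI	CO1
COX1	CO1
COXI	CO1
CO2	CO2
COII	CO2
COX2	CO2
COXII	CO2
CO3	CO3
COIII	CO3
COX3	CO3
COXIII	CO3
ATP6	ATP6
ATPASE6	ATP6
ATP8	ATP8
ATPASE8	ATP8
ND1	ND1
NAD1	ND1
NADH1	ND1
ND2	ND2
NAD2	ND2
NADH2	ND2
ND3	ND3
NAD3	ND3
NADH3	ND3
ND4	ND4
NAD4	ND4
NADH4	ND4
ND4L	ND4L
NAD4L	ND4L
NADH4L	ND4L
ND5	ND5
NAD5	ND5
NADH5	ND5
ND6	ND6
NAD6	ND6
NADH6	ND6
CYTB	CYTB
COB	CYTB
CYB	CYTB
CYTOCHROMEB	CYTB
LRRNA	lrRNA
RRNL	lrRNA
16S	lrRNA
16SRRNA	lrRNA
16SRIBOSOMALRNA	lrRNA
L-RRNA	lrRNA
LARGESUBUNITRIBOSOMALRNA	lrRNA
SRRNA	srRNA
RRNS	srRNA
12S	srRNA
12SRRNA	srRNA
12SRIBOSOMALRNA	srRNA
S-RRNA	srRNA
SMALLSUBUNITRIBOSOMALRNA	srRNA
CR	CR
D-LOOP	CR
DLOOP	CR
CONTROLREGION	CR
AT-RICHREGION	CR
A+T-RICHREGION	CR
TRNI	trnI
TRNA-ILE	trnI
TRNQ	trnQ
TRNA-GLN	trnQ
TRNM	trnM
TRNA-MET	trnM
TRNW	trnW
TRNA-TRP	trnW
TRNC	trnC
TRNA-CYS	trnC
TRNY	trnY
TRNA-TYR	trnY
TRNL2	trnL2
TRNL(UUR)	trnL2
TRNA-LEU(UUR)	trnL2
TRNA-LEU2	trnL2
TRNK	trnK
TRNA-LYS	trnK
TRND	trnD
TRNA-ASP	trnD
TRNG	trnG
TRNA-GLY	trnG
TRNA	trnA
TRNA-ALA	trnA
TRNR	trnR
TRNA-ARG	trnR
TRNN	trnN
TRNA-ASN	trnN
TRNS1	trnS1
TRNS(AGN)	trnS1
TRNA-SER(AGN)	trnS1
TRNA-SER1	trnS1
TRNE	trnE
TRNA-GLU	trnE
TRNF	trnF
TRNA-PHE	trnF
TRNH	trnH
TRNA-HIS	trnH
TRNT	trnT
TRNA-THR	trnT
TRNP	trnP
TRNA-PRO	trnP
TRNS2	trnS2
TRNS(UCN)	trnS2
TRNA-SER(UCN)	trnS2
TRNA-SER2	trnS2
TRNL1	trnL1
TRNL(CUN)	trnL1
TRNA-LEU(CUN)	trnL1
TRNA-LEU1	trnL1
TRNV	trnV
TRNA-VAL	trnV
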