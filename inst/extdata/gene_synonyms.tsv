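# Feature-name synonym table: GenBank /gene and /product dialects mapped to
# the canonical vocabulary. Keys are matched case-insensitively after
# trimming. Plain "tRNA-Leu"/"tRNA-Ser" map to the first canonical copy
# (trnL2/trnS2); the reader promotes a second occurrence to trnL1/trnS1.
alias	canonical
COI	COI
CO1	COI
COX1	COI
COXI	COI
COX-1	COI
CYTOCHROME C OXIDASE SUBUNIT 1	COI
CYTOCHROME C OXIDASE SUBUNIT I	COI
COII	COII
CO2	COII
COX2	COII
COXII	COII
CYTOCHROME C OXIDASE SUBUNIT 2	COII
CYTOCHROME C OXIDASE SUBUNIT II	COII
COIII	COIII
CO3	COIII
COX3	COIII
COXIII	COIII
CYTOCHROME C OXIDASE SUBUNIT 3	COIII
CYTOCHROME C OXIDASE SUBUNIT III	COIII
CYTB	CYTB
COB	CYTB
CYB	CYTB
CYTOCHROME B	CYTB
ATP6	ATP6
ATPASE6	ATP6
ATPASE 6	ATP6
ATP SYNTHASE F0 SUBUNIT 6	ATP6
ATP8	ATP8
ATPASE8	ATP8
ATPASE 8	ATP8
ATP SYNTHASE F0 SUBUNIT 8	ATP8
ND1	ND1
NAD1	ND1
NADH DEHYDROGENASE SUBUNIT 1	ND1
ND2	ND2
NAD2	ND2
NADH DEHYDROGENASE SUBUNIT 2	ND2
ND3	ND3
NAD3	ND3
NADH DEHYDROGENASE SUBUNIT 3	ND3
ND4	ND4
NAD4	ND4
NADH DEHYDROGENASE SUBUNIT 4	ND4
ND4L	ND4L
NAD4L	ND4L
NADH DEHYDROGENASE SUBUNIT 4L	ND4L
ND5	ND5
NAD5	ND5
NADH DEHYDROGENASE SUBUNIT 5	ND5
ND6	ND6
NAD6	ND6
NADH DEHYDROGENASE SUBUNIT 6	ND6
RRNS	rrnS
12S RIBOSOMAL RNA	rrnS
12S RRNA	rrnS
S-RRNA	rrnS
SMALL SUBUNIT RIBOSOMAL RNA	rrnS
RRNL	rrnL
16S RIBOSOMAL RNA	rrnL
16S RRNA	rrnL
L-RRNA	rrnL
LARGE SUBUNIT RIBOSOMAL RNA	rrnL
TRNA-PHE	trnF
TRNF	trnF
TRNA-VAL	trnV
TRNV	trnV
TRNA-LEU	trnL2
TRNA-LEU(UUR)	trnL2
TRNA-LEU (UUR)	trnL2
TRNL2	trnL2
TRNA-LEU(CUN)	trnL1
TRNA-LEU (CUN)	trnL1
TRNL1	trnL1
TRNA-ILE	trnI
TRNI	trnI
TRNA-GLN	trnQ
TRNQ	trnQ
TRNA-MET	trnM
TRNM	trnM
TRNA-TRP	trnW
TRNW	trnW
TRNA-ALA	trnA
TRNA	trnA
TRNA-ASN	trnN
TRNN	trnN
TRNA-CYS	trnC
TRNC	trnC
TRNA-TYR	trnY
TRNY	trnY
TRNA-SER	trnS2
TRNA-SER(UCN)	trnS2
TRNA-SER (UCN)	trnS2
TRNS2	trnS2
TRNA-SER(AGN)	trnS1
TRNA-SER (AGN)	trnS1
TRNS1	trnS1
TRNA-ASP	trnD
TRND	trnD
TRNA-LYS	trnK
TRNK	trnK
TRNA-GLY	trnG
TRNG	trnG
TRNA-ARG	trnR
TRNR	trnR
TRNA-HIS	trnH
TRNH	trnH
TRNA-GLU	trnE
TRNE	trnE
TRNA-THR	trnT
TRNT	trnT
TRNA-PRO	trnP
TRNP	trnP
D-LOOP	CR
D LOOP	CR
CONTROL REGION	CR
CR	CR
OL	OL
O_L	OL
L-STRAND ORIGIN	OL
ORIGIN OF L-STRAND REPLICATION	OL
ORIGIN OF LIGHT STRAND REPLICATION	OL
REPLICATION ORIGIN	OL
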