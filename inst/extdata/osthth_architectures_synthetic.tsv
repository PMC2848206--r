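# Synthetic OST-HTH architecture corpus (see ?osthth_architectures).
# A reconstruction, NOT a transcription of any published supplement: built
# only from domain fusions described in the OST-HTH literature, with category
# counts constrained to the reported neighborhood-linkage percentages.
protein_id	organism	lineage	domains
LKN1_Bjap	Bjap	Bacteria	LK-nuclease;OST-HTH
LKN1_Rpal	Rpal	Bacteria	LK-nuclease;OST-HTH
LKN1_Atha	Atha	Plants	LK-nuclease;OST-HTH
LKN1_Mbur	Mbur	Archaea	LK-nuclease;OST-HTH
LKN2_Neur	Neur	Bacteria	LK-nuclease;OST-HTH;OST-HTH
LKN3_Xaxo	Xaxo	Bacteria	DUF2384;LK-nuclease;OST-HTH
LKS1_Ssp	Ssp	Bacteria	LK-nuclease;OST-HTH;S1/CSD-OB
LKB1_Hsap	Hsap	Metazoa	LK-nuclease;OST-HTH;RRM
LKB2_Nvec	Nvec	Metazoa	LK-nuclease;OST-HTH;RRM;RRM
ORR1_Cele	Cele	Metazoa	OST-HTH;RRM
ORR2_Ptet	Ptet	Ciliates	RRM;OST-HTH
OKH1_Atha	Atha	Plants	OST-HTH;KH
OKH2_Osat	Osat	Plants	KH;OST-HTH
OCC1_Tthe	Tthe	Ciliates	OST-HTH;CCCH
OCC2_Pfal	Pfal	Apicomplexa	CCCH;OST-HTH
ODS1_Pinf	Pinf	Stramenopiles	OST-HTH;dsRBD
ODS2_Nvec	Nvec	Metazoa	dsRBD;OST-HTH
OZN1_Vvin	Vvin	Plants	OST-HTH;Zn-knuckle
ZLK1_Chut	Chut	Bacteria	Zn-knuckle;LK-nuclease;OST-HTH
OSB1_Daro	Daro	Bacteria	S1/CSD-OB;OST-HTH
OTU1_Hsap	Hsap	Metazoa	OST-HTH;Tudor
TDRD5_Hsap	Hsap	Metazoa	Tudor;OST-HTH
TDRD7_Hsap	Hsap	Metazoa	Tudor;OST-HTH
CG8920_Dmel	Dmel	Metazoa	OST-HTH;Tudor;Tudor
OTT1_Nvec	Nvec	Metazoa	OST-HTH;OST-HTH;Tudor
Oskar_Dmel	Dmel	Metazoa	OST-HTH;SGNH
OWW1_Cpar	Cpar	Apicomplexa	OST-HTH;WW
OWW2_Tthe	Tthe	Ciliates	WW;OST-HTH
OAN1_Atha	Atha	Plants	Ankyrin;OST-HTH
OMO1_Pinf	Pinf	Stramenopiles	OST-HTH;MORN
RAT1_Hsap	Hsap	Metazoa	RRM;OST-HTH;Tudor
RAT2_Nvec	Nvec	Metazoa	Tudor;OST-HTH;RRM
KAT1_Dmel	Dmel	Metazoa	KH;OST-HTH;Tudor
OTR1_Hsap	Hsap	Metazoa	OST-HTH;Tudor;RRM
CAW1_Ptet	Ptet	Ciliates	CCCH;OST-HTH;WW
OWK1_Tpar	Tpar	Apicomplexa	OST-HTH;WW;KH
DAN1_Osat	Osat	Plants	dsRBD;OST-HTH;Ankyrin
ZMO1_Pinf	Pinf	Stramenopiles	Zn-knuckle;OST-HTH;MORN
ORW1_Cpar	Cpar	Apicomplexa	OST-HTH;RRM;WW
SAT1_Nvec	Nvec	Metazoa	S1/CSD-OB;OST-HTH;Tudor
TKH1_Hsap	Hsap	Metazoa	Tudor;OST-HTH;KH
OSR1_Atha	Atha	Plants	OST-HTH;Sfi1;RRM
TTR1_Dmel	Dmel	Metazoa	Tudor;Tudor;OST-HTH;RRM
RSG1_Dmel	Dmel	Metazoa	RRM;OST-HTH;SGNH
RUR1_Ptet	Ptet	Ciliates	RING;OST-HTH;RRM
OUK1_Atha	Atha	Plants	OST-HTH;Ubl;KH
CUU1_Pinf	Pinf	Stramenopiles	CCCH;OST-HTH;U-box
TUR1_Nvec	Nvec	Metazoa	Tudor;OST-HTH;RING
WUU1_Tthe	Tthe	Ciliates	WW;OST-HTH;Ubl
ORN1_Vvin	Vvin	Plants	OST-HTH;RING
OUB1_Ptet	Ptet	Ciliates	U-box;OST-HTH
GSC1_Pinf	Pinf	Stramenopiles	RRM;Tudor;OST-HTH;RING
GSC2_Pinf	Pinf	Stramenopiles	KH;WW;OST-HTH;U-box
GSC3_Pinf	Pinf	Stramenopiles	RING;RRM;OST-HTH;Tudor
BCM1_Tthe	Tthe	Ciliates	B-Box;OST-HTH;CCCH;MORN
LDW1_Atha	Atha	Plants	Little-finger;OST-HTH;dsRBD;WW
UZA1_Osat	Osat	Plants	Ubl;OST-HTH;Zn-knuckle;Ankyrin
WLK1_Atha	Atha	Plants	WW;LK-nuclease
ZLK2_Bthe	Bthe	Bacteria	Zn-knuckle;LK-nuclease
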