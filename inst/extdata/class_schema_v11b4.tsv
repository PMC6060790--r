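class	category	family
GBM, RTK I	tumor	Glioblastoma, IDH wt
GBM, RTK II	tumor	Glioblastoma, IDH wt
GBM, RTK III	tumor	Glioblastoma, IDH wt
GBM, MES	tumor	Glioblastoma, IDH wt
GBM, MID	tumor	Glioblastoma, IDH wt
GBM, MYCN	tumor	Glioblastoma, IDH wt
A IDH	tumor	IDH glioma
A IDH, HG	tumor	IDH glioma
O IDH	tumor	IDH glioma
MB, SHH CHL AD	tumor	Medulloblastoma, SHH
MB, SHH INF	tumor	Medulloblastoma, SHH
MB, G3	tumor	Medulloblastoma, group 3/4
MB, G4	tumor	Medulloblastoma, group 3/4
LGG, PA PF	tumor	Pilocytic astrocytoma
LGG, PA MID	tumor	Pilocytic astrocytoma
LGG, PA/GG ST	tumor	Pilocytic astrocytoma
PLEX, AD	tumor	Plexus tumor
PLEX, PED A	tumor	Plexus tumor
PLEX, PED B	tumor	Plexus tumor
ATRT, MYC	tumor	ATRT
ATRT, SHH	tumor	ATRT
ATRT, TYR	tumor	ATRT
PITAD, ACTH	tumor	Pituitary adenoma
PITAD, FSH LH	tumor	Pituitary adenoma
PITAD, PRL	tumor	Pituitary adenoma
PITAD, STH DNS A	tumor	Pituitary adenoma
PITAD, STH DNS B	tumor	Pituitary adenoma
PITAD, STH SPA	tumor	Pituitary adenoma
DMG, K27	tumor
GBM, G34	tumor
ANA PA	tumor
PXA	tumor
LGG, SEGA	tumor
LGG, MYB	tumor
LGG, GG	tumor
LGG, DNT	tumor
LGG, RGNT	tumor
LGG, DIG/DIA	tumor
DLGNT	tumor
CN	tumor
EVN, CYN	tumor
LIPN	tumor
PGG, nC	tumor
ENB, A	tumor
ENB, B	tumor
EPN, PF A	tumor
EPN, PF B	tumor
EPN, RELA	tumor
EPN, YAP	tumor
EPN, MPE	tumor
EPN, SPINE	tumor
SUBEPN, PF	tumor
SUBEPN, ST	tumor
SUBEPN, SPINE	tumor
CHGL	tumor
HGNET, BCOR	tumor
HGNET, MN1	tumor
CNS NB, FOXR2	tumor
EFT, CIC	tumor
ETMR	tumor
MB, WNT	tumor
PIN T, PB A	tumor
PIN T, PB B	tumor
PIN T, PPT	tumor
PTPR, A	tumor
PTPR, B	tumor
CPH, ADM	tumor
CPH, PAP	tumor
PITUI	tumor
MNG	tumor
HMB	tumor
SFT HMPC	tumor
EWS	tumor
CHORDM	tumor
MELAN	tumor
MELCYT	tumor
SCHW	tumor
SCHW, MEL	tumor
MPNST	tumor
LYMPHO	tumor
PLASMA	tumor
RETB	tumor
CONTR, ADENOPIT	control
CONTR, CEBM	control
CONTR, HEMI	control
CONTR, HYPTHAL	control
CONTR, INFLAM	control
CONTR, PINEAL	control
CONTR, PONS	control
CONTR, REACT	control
CONTR, WM	control
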