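gene	category	variant_label	patient_id	rsid	control_carriers	validated
ABCC11	splice_site	NM_032583.3:c.395+2T>C(p.?)	BB44	.	0	TRUE
ABCC11	nonsense	NM_032583.3:c.297G>A(p.Trp99*)	BB12	rs145048685	1	TRUE
BARD1	nonsense	NM_000465.3:c.1690C>T(p.Gln564*)	BB13	rs587780021	0	TRUE
BBS10	frameshift_indel	NM_024685.3:c.271dup(p.Cys91Leufs*5)	BB15	rs549625604	1	TRUE
BBS10	frameshift_indel	NM_024685.3:c.1543_1546dup(p.Thr516Argfs*7)	BB48	.	0	TRUE
CCNH	frameshift_indel	NM_001239.3:c.643_646del(p.Thr215Profs*21)	BB15	.	0	TRUE
CD96	frameshift_indel	NM_198196.2:c.766dup(p.Ile256Asnfs*13)	BB10	rs766366613	0	TRUE
CD96	nonsense	NM_198196.2:c.1321C>T(p.Arg441*)	BB54	rs201691670	0	TRUE
CHEK2	frameshift_indel	NM_001005735.1:c.1229del(p.Thr410Metfs*15)	BB17	rs555607708	0	TRUE
CYP1A1	frameshift_indel	NM_000499.3:c.1371del(p.Cys457*)	BB1	rs561096394	0	TRUE
DCLRE1A	nonsense	NM_001271816.1:c.412C>T(p.Arg138*)	BB41	rs41292634	0	TRUE
DCLRE1C	nonsense	NM_001033855.2:c.241C>T(p.Arg81*)	BB33	rs121908156	0	TRUE
DHCR7	splice_site	NM_001360.2:c.964-1G>C(p.?)	BB21	rs138659167	0	TRUE
DNAH11	frameshift_indel	NM_001277115.1:c.2081_2082del(p.Val694Glyfs*2)	BB29	.	0	TRUE
ESCO2	frameshift_indel	NM_001017420.2:c.876_879del(p.Asp292Glufs*48)	BB35	rs80359856	0	TRUE
EXO1	splice_site	NM_006027.4:c.2212-1G>C(p.?)	BB35	rs4150000	0	TRUE
FANCA	splice_site	NM_000135.2:c.2152-2A>G(p.?)	BB45	.	0	TRUE
FLT4	nonsense	NM_182925.4:c.3048C>A(p.Cys1016*)	BB38	.	0	TRUE
HPS6	stop_loss	NM_024747.5:c.2326T>C(p.*776Argext*38)	BB33	rs200206362	0	TRUE
MUS81	nonsense	NM_025128.4:c.392G>A(p.Trp131*)	BB7	.	0	TRUE
MYH8	nonsense	NM_002472.2:c.1209C>A(p.Cys403*)	BB31	rs144321381	0	TRUE
NME8	splice_site	NM_016616.4:c.454+1G>A(p.?)	BB3	rs538425312	0	TRUE
NME8	nonsense	NM_016616.4:c.1600C>T(p.Arg534*)	BB33	rs142525551	0	TRUE
PALB2	frameshift_indel	NM_024675.3:c.1674dup(p.Gln559Serfs*19)	BB36	.	0	TRUE
PDE11A	frameshift_indel	NM_016953.3:c.1660del(p.Cys554Valfs*14)	BB5	rs573163079	1	TRUE
RAD51C	frameshift_indel	NM_058216.2:c.181_182del(p.Leu61Alafs*11)	BB54	rs754525165	0	TRUE
RECQL4	frameshift_indel	NM_004260.3:c.1573del(p.Cys525Alafs*33)	BB52	rs386833845	0	TRUE
RECQL4	frameshift_indel	NM_004260.3:c.3439del(p.Leu1147Cysfs*3)	BB34	.	0	TRUE
RINT1	nonsense	NM_021930.4:c.64G>T(p.Glu22*)	BB3	.	0	TRUE
TDP1	frameshift_indel	NM_018319.3:c.502del(p.Leu168Serfs*45)	BB32	rs762302264	0	TRUE
TTC8	nonsense	NM_001288781.1:c.736C>T(p.Gln246*)	BB29	.	0	TRUE
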