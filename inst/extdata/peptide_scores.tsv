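peptide	score
QGL	0.533495
QM	0.607122
STF	0.58977
CPL	0.916551
VIW	0.610494
SF	0.948796
GY	0.741592
SM	0.628268
QPM	0.810167
PQL	0.527882
QF	0.946135
PSGAW	0.870583
PL	0.811148
AAM	0.55858
ACL	0.746733
PF	0.99343
PVEPF	0.604782
QPPQPL	0.823819
DM	0.607466
PIQAF	0.749093
GPF	0.989324
PIL	0.641797
IF	0.949173
PR	0.787626
PY	0.736696
PW	0.992911
AGAF	0.873661
AGPF	0.969222
AW	0.9669
AM	0.74549
AIPY	0.613395
GL	0.808777
QW	0.928524
PH	0.541688
AIPPK	0.575607
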