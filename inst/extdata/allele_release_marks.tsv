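peptide	gene	allele
QGL	CSN1S1	A
QGL	CSN1S1	B
QGL	CSN1S1	E
QGL	CSN1S1	F
QM	CSN1S1	A
QM	CSN1S1	B
QM	CSN1S1	E
QM	CSN1S1	F
STF	CSN1S1	F
CPL	CSN1S1	F
VIW	CSN1S1	F
SF	CSN1S1	F
SF	CSN3	A
SF	CSN3	B
SF	CSN3	C
SF	CSN3	D
SF	CSN3	E
GY	CSN1S1	A
GY	CSN1S1	B
GY	CSN1S1	E
SM	CSN1S1	A
SM	CSN1S1	B
SM	CSN1S1	E
QPM	CSN1S1	A
QPM	CSN1S1	B
QPM	CSN1S1	E
PQL	CSN1S1	A
PQL	CSN1S1	B
PQL	CSN1S1	E
QF	CSN1S1	A
QF	CSN1S1	B
QF	CSN1S1	E
QF	CSN1S2	A
QF	CSN1S2	B
QF	CSN1S2	C
QF	CSN1S2	F
QF	CSN3	A
QF	CSN3	B
QF	CSN3	C
QF	CSN3	D
QF	CSN3	E
PSGAW	CSN1S1	A
PSGAW	CSN1S1	B
PSGAW	CSN1S1	E
PL	CSN1S1	A
PL	CSN1S1	B
PL	CSN1S1	E
PL	CSN2	A
PL	CSN2	C
AAM	CSN1S1	E
ACL	CSN2	A
ACL	CSN2	C
PF	CSN2	A
PF	CSN2	C
PVEPF	CSN2	A
PVEPF	CSN2	C
QPPQPL	CSN2	A
QPPQPL	CSN2	C
DM	CSN2	A
DM	CSN2	C
PIQAF	CSN2	A
PIQAF	CSN2	C
GPF	CSN2	A
GPF	CSN2	C
PIL	CSN2	A
PIL	CSN2	C
IF	CSN1S2	A
IF	CSN1S2	B
IF	CSN1S2	C
IF	CSN1S2	F
PR	CSN1S2	A
PR	CSN1S2	B
PR	CSN1S2	C
PR	CSN1S2	F
PY	CSN1S2	A
PY	CSN1S2	B
PY	CSN1S2	C
PY	CSN1S2	F
PY	CSN3	A
PY	CSN3	B
PY	CSN3	C
PY	CSN3	D
PY	CSN3	E
PW	CSN1S2	A
PW	CSN1S2	B
PW	CSN1S2	C
PW	CSN1S2	F
AGAF	CSN1S2	A
AGAF	CSN1S2	B
AGAF	CSN1S2	C
AGPF	CSN1S2	F
AW	CSN1S2	A
AW	CSN1S2	B
AW	CSN1S2	C
AW	CSN1S2	F
AM	CSN1S2	A
AM	CSN1S2	B
AM	CSN1S2	C
AM	CSN1S2	F
AIPY	CSN1S2	A
AIPY	CSN1S2	B
AIPY	CSN1S2	C
AIPY	CSN1S2	F
GL	CSN3	A
GL	CSN3	B
GL	CSN3	C
GL	CSN3	D
GL	CSN3	E
QW	CSN3	A
QW	CSN3	B
QW	CSN3	C
QW	CSN3	D
QW	CSN3	E
PH	CSN3	A
PH	CSN3	B
PH	CSN3	C
PH	CSN3	D
PH	CSN3	E
AIPPK	CSN3	A
AIPPK	CSN3	B
AIPPK	CSN3	C
AIPPK	CSN3	D
AIPPK	CSN3	E
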