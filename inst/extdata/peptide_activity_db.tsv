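peptide	activity_code
QGL	ACE-I
QGL	DPP-IV-I
STF	ACE-I
STF	H
STF	DPP-IV-I
STF	DPP-III-I
STF	R-I
STF	P-L-I
CPL	ACE-I
CPL	DPP-IV-I
CPL	X-P-I
CPL	L-I
VIW	ACE-I
VIW	DPP-IV-I
SF	ACE-I
SF	DPP-IV-I
SF	R-I
GY	ACE-I
GY	DPP-IV-I
GY	DPP-III-I
SM	DPP-III-I
QPM	ACE-I
QPM	DPP-IV-I
PQL	ACE-I
PQL	DPP-IV-I
QF	DPP-IV-I
QF	R-I
PSGAW	ACE-I
PSGAW	AO
PSGAW	I
PSGAW	DPP-IV-I
PSGAW	A-C-I
PL	ACE-I
PL	DPP-IV-I
PL	X-P-I
PL	L-I
AAM	ACE-I
AAM	A-B
AAM	H
AAM	DPP-IV-I
AAM	I-TPP-II
AAM	I-C-A-AP
AAM	D-A-D-DP-I
PF	DPP-IV-I
PF	DPP-III-I
PF	ACE2-I
PVEPF	ACE-I
PVEPF	AO
PVEPF	DPP-IV-I
PVEPF	A-G-I
PVEPF	DPP-III-I
PVEPF	ACE2-I
PVEPF	N-I
QPPQPL	ACE-I
QPPQPL	DPP-IV-I
QPPQPL	A-G-I
QPPQPL	X-P-I
QPPQPL	L-I
DM	ACE-I
PIQAF	ACE-I
PIQAF	DPP-IV-I
PIQAF	I-TPP-II
GPF	AAM
GPF	ACE-I
GPF	AT
GPF	RL
GPF	AO
GPF	H
GPF	DPP-IV-I
GPF	DPP-III-I
GPF	ACE2-I
GPF	N-I
PIL	ACE-I
PIL	S
PIL	NP
PIL	DPP-IV-I
IF	ACE-I
PR	ACE-I
PR	DPP-III-I
PY	NP
PY	A-I
PY	DPP-IV-I
PY	PL-A2-I
PW	AO
PW	DPP-IV-I
AGAF	ACE-I
AGAF	AO
AGAF	DPP-IV-I
AGAF	CaMPDE-I
AGAF	I-TPP-II
AGAF	A-C-I
AGPF	AAM
AGPF	ACE-I
AGPF	AT
AGPF	RL
AGPF	AO
AGPF	DPP-IV-I
AGPF	DPP-III-I
AGPF	ACE2-I
AGPF	N-I
AW	ACE-I
AW	AO
AW	DPP-IV-I
AIPY	ACE-I
AIPY	NP
AIPY	A-I
AIPY	DPP-IV-I
AIPY	PL-A2-I
GL	ACE-I
GL	DPP-IV-I
QW	DPP-IV-I
PH	ACE-I
PH	DPP-IV-I
PH	AO
AIPPK	A-A-I
AIPPK	ACE-I
AIPPK	AT
AIPPK	AO
AIPPK	A-I
AIPPK	DPP-IV-I
AIPPK	A-G-I
AIPPK	ACE2-I
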