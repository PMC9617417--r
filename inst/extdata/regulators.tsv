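gene_id	is_lncrna	mhc1_coding	regulator_class	regulator_role
PUS1	FALSE	FALSE	psi	writer
PUS3	FALSE	FALSE	psi	writer
PUS7	FALSE	FALSE	psi	writer
PUS7L	FALSE	FALSE	psi	writer
PUS10	FALSE	FALSE	psi	writer
RPUSD1	FALSE	FALSE	psi	writer
RPUSD2	FALSE	FALSE	psi	writer
RPUSD3	FALSE	FALSE	psi	writer
RPUSD4	FALSE	FALSE	psi	writer
DKC1	FALSE	FALSE	psi	writer
TRUB1	FALSE	FALSE	psi	writer
TRUB2	FALSE	FALSE	psi	writer
NSUN1	FALSE	FALSE	m5C	writer
NSUN2	FALSE	FALSE	m5C	writer
NSUN3	FALSE	FALSE	m5C	writer
NSUN4	FALSE	FALSE	m5C	writer
NSUN5	FALSE	FALSE	m5C	writer
NSUN6	FALSE	FALSE	m5C	writer
NSUN7	FALSE	FALSE	m5C	writer
TRDMT1	FALSE	FALSE	m5C	writer
ALYREF	FALSE	FALSE	m5C	reader
YBX1	FALSE	FALSE	m5C	reader
TET2	FALSE	FALSE	m5C	eraser
TRMT6	FALSE	FALSE	m1A	writer
TRMT61A	FALSE	FALSE	m1A	writer
TRMT61B	FALSE	FALSE	m1A	writer
TRMT10C	FALSE	FALSE	m1A	writer
YTHDF3	FALSE	FALSE	m1A	reader
YTHDC1	FALSE	FALSE	m1A	reader
ALKBH1	FALSE	FALSE	m1A	eraser
ALKBH3	FALSE	FALSE	m1A	eraser
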