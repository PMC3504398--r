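PIRIN	WNT5A
S100P	WNT5A
MART1	WNT5A
S100P	PIRIN
RET1	PIRIN
HADHB	PIRIN
RET1	S100P
MART1	S100P
STC2	S100P
MART1	RET1
HADHB	RET1
MMP3	RET1
HADHB	MART1
STC2	MART1
PHOC	MART1
STC2	HADHB
MMP3	HADHB
SNCA	HADHB
MMP3	STC2
PHOC	STC2
WNT5A	STC2
PHOC	MMP3
SNCA	MMP3
PIRIN	MMP3
SNCA	PHOC
WNT5A	PHOC
S100P	PHOC
WNT5A	SNCA
PIRIN	SNCA
RET1	SNCA
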