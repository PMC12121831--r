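label	expression
SYN 1	_CARDI & VASCUL
SYN 2	{CHRONIC | ACUTE} & CONDITIONS
SYN 3	HYPERTENS | BLOOD | ARTERIAL & PRESSURE
SYN 4	~INJURY
SYN 5	{WOMEN | _FEMAL} & {~CANCER}
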