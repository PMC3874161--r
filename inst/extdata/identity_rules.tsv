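synthetase	element	value
AlaRS	pair3_70	G:U
HisRS	minus1	G
HisRS	base73	C
HisRS	anticodon	GUG
ThrRS-MST1	loop_len	8
ThrRS-MST1	loop_ins_U31	TRUE
ThrRS-MST1	anticodon	UAG
LeuRS	base73	A
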