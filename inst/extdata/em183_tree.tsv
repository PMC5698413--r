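child	parent	variants
M183	ROOT	M183
SM001	M183	SM001
PF6794	SM001	PF6794
PF6789	PF6794	PF6789
CTS12227	SM001	CTS12227
Z5009	SM001	Z5009
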