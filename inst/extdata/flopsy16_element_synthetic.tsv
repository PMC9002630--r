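flip_deg	phase_sign
245	1
390	-1
265	1
95	-1
130.04	1
95	-1
265	1
390	-1
245	1
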