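raw	canonical
BAVENCIO	AVELUMAB
Bavencio	AVELUMAB
AVELUMAB (BAVENCIO)	AVELUMAB
MSB0010718C	AVELUMAB
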