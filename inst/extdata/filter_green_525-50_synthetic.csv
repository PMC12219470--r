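wavelength_nm,value
499,0
500,0.95
550,0.95
551,0
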