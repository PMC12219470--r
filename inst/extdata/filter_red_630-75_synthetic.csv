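wavelength_nm,value
592,0
592.5,0.95
667.5,0.95
668,0
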