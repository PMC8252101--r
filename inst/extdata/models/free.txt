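# Free model: all 20 transition rates among the five coupled states
# (AU-R, AU-ES, AU-RES, MH-RES, MH-ES) are independent; no constraints.
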