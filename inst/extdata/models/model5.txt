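# Model 4 plus: reversals from full mycoheterotrophy to autotrophy only
# occur from the mixed association (MH-RES); MH-ES cannot revert directly.
# Reconstruction constrained to the published free-parameter count (12).
AU-R	MH-RES
AU-R	MH-ES
AU-ES	MH-RES
AU-ES	MH-ES
AU-RES	MH-ES
MH-ES	AU-R
MH-ES	AU-ES
MH-ES	AU-RES
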