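# Model 5 plus: a reversal cannot jump straight to the rhizoctonia-only
# state (no MH-RES -> AU-R), so regaining photosynthesis and losing all
# ECM/SAP partners never coincide (11 free parameters).
AU-R	MH-RES
AU-R	MH-ES
AU-ES	MH-RES
AU-ES	MH-ES
AU-RES	MH-ES
MH-ES	AU-R
MH-ES	AU-ES
MH-ES	AU-RES
MH-RES	AU-R
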