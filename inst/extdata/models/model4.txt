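# Forward transitions from autotrophy to full mycoheterotrophy require the
# mixed symbiotic association as an obligate intermediate: the only allowed
# entry is AU-RES -> MH-RES (15 free parameters).
AU-R	MH-RES
AU-R	MH-ES
AU-ES	MH-RES
AU-ES	MH-ES
AU-RES	MH-ES
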