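# Shifts to full mycoheterotrophy are possible only from the
# ECM/SAP-only autotrophic state (AU-ES). Reconstruction constrained to
# the published free-parameter count (16).
AU-R	MH-RES
AU-R	MH-ES
AU-RES	MH-RES
AU-RES	MH-ES
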