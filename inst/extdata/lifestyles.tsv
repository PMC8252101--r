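family	lifestyle
Tulasnellaceae	RHI
Ceratobasidiaceae	RHI
Serendipitaceae	RHI
Sebacinaceae	ECM
Thelephoraceae	ECM
Russulaceae	ECM
Tuberaceae	ECM
Clavulinaceae	ECM
Hymenogastraceae	ECM
Inocybaceae	ECM
Pezizaceae	ECM/SAP
Pyronemataceae	ECM/SAP
Hymenochaetaceae	SAP
Marasmiaceae	SAP
Psathyrellaceae	SAP
Mycenaceae	SAP
Physalacriaceae	SAP
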