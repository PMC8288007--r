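go_id	keyword	main_function
GO:0016020	membrane	homeostasis
GO:0043167	ion binding	homeostasis
GO:0005833	blood	homeostasis
GO:0008152	metabolic	energy_production
GO:0005524	ATP	energy_production
GO:0016740	transferase	energy_production
GO:0010468	regulation of gene expression	protein_production
GO:0006412	translation	protein_production
GO:0005515	protein binding	protein_binding
GO:0003779	actin	actin
GO:0007165	signal transduction	signal_transduction
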