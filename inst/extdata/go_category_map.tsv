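go_id	category
GO:0016021	membrane_component
GO:0016020	membrane_component
GO:0032991	complexes
GO:0003824	enzymes
GO:0016740	enzymes
GO:0016787	enzymes
GO:0005739	mitochondrion
GO:0005783	endoplasmic_reticulum
GO:0008270	cation_binding
GO:0000287	cation_binding
GO:0005507	cation_binding
GO:0050897	cation_binding
GO:0005794	golgi
GO:0048870	cell_movement
GO:0005524	adp_atp_binding
GO:0043531	adp_atp_binding
GO:0003677	dna_rna_binding
GO:0003723	dna_rna_binding
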