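interferon_alpha_response	curated synthetic panel, editable	ISG15	IFI6	IFITM3	B2M	IRF1	GBP1
interferon_gamma_response	curated synthetic panel, editable	STAT1	IRF1	GBP1	CD74	CCL20	CCL25	HLA-DRA	HLA-DPA1
exhausted_ligands	curated synthetic panel, editable	LGALS3	CEACAM1	NECTIN4	HLA-B
costimulatory_ligands	curated synthetic panel, editable	MYL9	TNFSF10
neuroendocrine_markers	curated synthetic panel, editable	CGA	CHGA	CHGB	APOA1
differentiation_signature	curated synthetic panel, editable	AGR3	CLDN3	CLDN4	FABP1	LGALS4	PHGR1	MYH14	S100A14
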