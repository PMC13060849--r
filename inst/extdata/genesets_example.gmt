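RTK_SIGNALING	receptor tyrosine kinases	EGFR	ERBB2	ERBB3	MET	PDGFRA	ROR2	PTK7
CELL_MIGRATION	migration and invasion receptors	ITGA4	ITGA1	PLXNA2	PCDH1
IMMUNE_SURFACE	immune-related surface proteins	CD70	NT5E	TACSTD2
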