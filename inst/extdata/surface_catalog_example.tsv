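# Example surface-protein catalog subset (id <tab> confidence)
EGFR	high
ERBB2	high
ERBB3	high
MET	high
PTK7	high
ROR2	high
ITGA4	high
ITGA1	high
PLXNA2	high
PCDH1	high
PDGFRA	high
CD70	high
TACSTD2	high
NT5E	putative
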