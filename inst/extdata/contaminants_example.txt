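# Example mass-spectrometry contaminant list (cRAP-style subset)
HSPA5
HSPA9
KRT1
KRT2
KRT9
KRT10
ALB
TRY1
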