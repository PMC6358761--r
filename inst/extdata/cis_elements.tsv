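# PLACE cis-element library used for trihelix promoter analysis.
# Editable: id, IUPAC consensus, functional annotation.
id	consensus	annotation
GATABOX	GATA	light_responsive
ACGTATERD1	ACGT	dehydration_responsive
GT1CONSENSUS	GRWAAW	light_responsive
INRNTPSADB	YTCANTYY	light_responsive
GT1GMSCAM4	GAAAAA	dehydration_responsive
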