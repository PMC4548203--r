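# PharmGKB-dialect relation fixture (synthetic associated-gene sample).
relation_type	gene	drug_id	drug_name	partner
gene_drug	ACE	PA0001	lisinopril	
gene_drug	PTGS2	PA0002	celecoxib	
gene_drug	SERPINE1	PA0003	urokinase	
gene_drug	THBS1	PA0004	associmycin	
gene_drug	AGTR1	PA0005	losartan	
gene_disease	SERPINE1			peripheral arterial disease
gene_disease	ACE			hypertension
gene_gene	TNF			IL6
gene_gene	SERPINE1			PLAT
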