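drug_name	target	degree_angiome	mechanism	original_use
Alteplase	SERPINE1	14	Plasminogen activator	Acute ischemic stroke
Danazol	CCL2	12	Synthetic steroid with antigonadotropic and anti-estrogenic activities	Endometriosis
Nitroprusside	NPR1	4	A source of nitric oxide, a potent peripheral vasodilator	Hypertensive emergency
Isosorbide dinitrate	NPR1	4	Vasodilator	Angina pectoris
Nesiritide	NPR1	4	Recombinant form of brain natriuretic peptide	Heart failure
Carvedilol	NPPB	3	Beta-1 and beta-2 adrenergic receptors blocker	Congestive heart failure
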