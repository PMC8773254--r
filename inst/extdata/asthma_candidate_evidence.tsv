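drug	gene	action	indication	phase	registry_or_pub_id	preclinical_flag
Gabapentin	ADORA1	Agonist	Postherpetic neuralgia	Phase IV	NCT00153283	false
Lamotrigine	ADORA1	Inhibitor	Epilepsy	Phase IV	NCT00153244	false
Simvastatin	HMGCR	Inhibitor	Hypercholesterolemia	Phase III	NCT01266434	false
Ketamine	NOS1	Inhibitor	General anaesthesia	Phase III	NCT03338205	false
Atorvastatin	HMGCR	Inhibitor	Hypercholesterolemia	Phases II/III	NCT00126048	false
Imatinib	BCR	Inhibitor	Chronic myelogenous leukaemia	Phase II	NCT01097694	false
Abatacept	CD86	Antagonist	Rheumatoid arthritis	Phase II	NCT00784459	false
Duvelisib	PIK3CB	Inhibitor	Small lymphocytic lymphoma	Phase II	NCT01653756	false
Adenosine	ADORA1	Agonist	Tachycardia	Phase II	NCT01006655	false
Rosuvastatin	HMGCR	Inhibitor	Hypercholesterolemia	Phase I	NCT01411111	false
Tocilizumab	IL6R	Inhibitor	Rheumatoid arthritis	Phases I/II	ACTRN12614000123640|25930193|30885880	false
Caffein	ADORA1	Inhibitor	Apnea of prematurity	NA	NCT01057875	false
Pentoxifylline	ADORA1		Intermittent claudication	-	19905913	true
Pitavastatin	HMGCR	Inhibitor	Hypercholesterolemia	-	28729731	true
Pravastatin	HMGCR	Inhibitor	Hypercholesterolemia	-	18835962	true
Lovastatin	HMGCR	Inhibitor	Hypercholesterolemia	-	25374755	true
Fluvastatin	HMGCR	Inhibitor	Hypercholesterolemia	-	16630152	true
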