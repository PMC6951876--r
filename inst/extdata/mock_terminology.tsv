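# Synthetic mock terminology for tests and examples. Identifiers imitate the
# CUI format of large medical metathesauri but the table is hand-written and
# packaged here; it is NOT an extract of any licensed resource.
# id	preferred_label	synonyms	semantic_tags
C1867423	Increased pulmonary vascular resistance		Problem
C0948755	Pulmonary failure	lung failure|respiratory failure	Condition
C0225860	Left atrium		AnatomicalConcept
C0556501	Upper limb training		Treatment
C0037981	Spirometry test	spirometry	TestOrMeasure
C1455997	Genetic susceptibility to disease		RiskFactor
C0852710	High oxygen saturation		TestOrMeasureResult
C0013404	Dyspnea	shortness of breath|breathlessness	SignOrSymptom
C0034067	Pulmonary emphysema	emphysema	Condition
C0010200	Chronic cough	cough, chronic	SignOrSymptom
C0004096	Asthma		Condition
C0149783	Inhaled corticosteroids	corticosteroids, inhaled	Treatment|Drug
C0184633	Oxygen supplementation	oxygen therapy	Treatment
C0032231	Pleuritis	pleural inflammation	Condition
C0225701	Alveolar septum	alveolar septa	AnatomicalConcept
C0001443	Alpha-1-antitrypsin	alpha1 antitrypsin	Protein
C0006277	Bronchitis	chronic bronchitis	Condition
C0024109	Lung	pulmonary|lungs	AnatomicalConcept
C0037313	Smoking	tobacco smoking	IndividualBehaviour
C0024117	Chronic obstructive pulmonary disease	COPD	Condition
C0016529	Forced expiratory volume in 1 second	FEV1	TestOrMeasure
C0429862	Decreased pulmonary function	decrease in rate of lung function	TestOrMeasureResult
C0332285	Deterioration of pulmonary function	worsening pulmonary function	TestOrMeasureResult
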