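label	parent
Problem	-
Condition	Problem
RiskFactor	Problem
SignOrSymptom	Problem
IndividualBehaviour	Problem
TestOrMeasureResult	Problem
Treatment	-
TestOrMeasure	-
RadiologicalTest	TestOrMeasure
MicrobiologicalTest	TestOrMeasure
PhysiologicalTest	TestOrMeasure
ConstituentConcept	-
AnatomicalConcept	ConstituentConcept
Drug	ConstituentConcept
Protein	ConstituentConcept
Quality	ConstituentConcept
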