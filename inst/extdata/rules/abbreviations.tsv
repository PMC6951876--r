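# abbreviation -> expansion (one per line, tab separated)
DM	diabetes mellitus
PVR	pulmonary vascular resistance
FEV1	forced expiratory volume in 1 second
FVC	forced vital capacity
TB	tuberculosis
CT	computed tomography
COPD	chronic obstructive pulmonary disease
CRP	C-reactive protein
O2	oxygen
BMI	body mass index
6MWD	6-min walking distance
ICS	inhaled corticosteroids
LABA	long-acting beta agonists
PFT	pulmonary function test
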