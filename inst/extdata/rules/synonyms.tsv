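# phrase -> substitute (word-boundary matched, case-insensitive)
# phrase	substitute
worsening	deterioration of
arm	upper limb
predisposition	susceptibility to disease
elevated	increased
elevation of	increased
reduced	decreased
failure	insufficiency
lung function	pulmonary function
breathlessness	dyspnea
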