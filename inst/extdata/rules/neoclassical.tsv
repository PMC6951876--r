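# neoclassical term <-> everyday-English equivalent; applied left-to-right
# for neoclassical->English generation and right-to-left for the reverse
# neoclassical	english
leukocyte	white blood cell
pulmonary	lung
cardiac	heart
hepatic	liver
renal	kidney
thoracic	chest
erythrocyte	red blood cell
gastric	stomach
dyspnea	shortness of breath
pleuritis	pleural inflammation
nephritis	kidney inflammation
hepatitis	liver inflammation
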