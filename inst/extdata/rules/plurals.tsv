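# plural -> singular; kind "token" entries match whole tokens,
# kind "suffix" entries are regular-expression suffix rules applied per token
# kind	pattern	replacement
token	septa	septum
token	alveoli	alveolus
token	bronchi	bronchus
token	vertebrae	vertebra
token	data	datum
token	criteria	criterion
token	bacteria	bacterium
suffix	([a-z])ies$	\1y
suffix	([a-z])ches$	\1ch
suffix	([a-z])sses$	\1ss
suffix	([a-z][^sua])s$	\1
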