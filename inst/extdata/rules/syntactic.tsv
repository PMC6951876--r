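# syntactic / term-variation patterns: full-string regular expressions
# pattern	replacement
^(\w+?)al (\w+)$	\2 \1ation
^(\w+) (\w+?)ation$	\2al \1
^(\w+) of (?:the )?(\w+)$	\2 \1
^(\w+) (\w+)$	\2 of \1
^(.*\w)ial$	\1ium
^(.*\w)tric$	\1try
^(.*\w)ic (\w+)$	\1y \2
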