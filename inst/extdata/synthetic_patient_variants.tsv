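patient	gene	MUTATION_EFFECT
P1	FLT3	Gain-of-function
P1	TP53	Loss-of-function
P2	FLT3	Gain-of-function
P2	JNK	Gain-of-function
P3	FLT3	Likely Gain-of-function
P3	DNMT3A	Unknown
P4	FLT3	Gain-of-function
P4	PI3K	Likely Gain-of-function
P5	FLT3	Gain-of-function
P5	IDH1	Inconclusive
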