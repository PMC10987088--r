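Synthetic fixtures only. These tables are generated stand-ins shaped like
the patient inputs the workflow consumes (MAF-like variant annotations and
FLT3-ITD insertion positions); they correspond to no real individuals.
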