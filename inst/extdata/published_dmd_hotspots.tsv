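band	dmd
12q12	32.9833
14q32.33	24.5667
15q26.3	22.3000
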