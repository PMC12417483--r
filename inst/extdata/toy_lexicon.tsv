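# toy sentiment lexicon (word<TAB>score); synthetic, for examples and tests
awful	-4
terrible	-4
angry	-3
rude	-2
slow	-1
unclear	-1
fine	1
helpful	2
kind	2
excellent	4
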