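sodium sulfate
anhydrous sodium sulfate
magnesium sulfate
anhydrous magnesium sulfate
calcium chloride
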