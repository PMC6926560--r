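category,percent
vulnerable,7.9
nonclass_normalSoC_highGHQ,0
nonclass_lowSoC_normalGHQ,60.2
resilient,31.8
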