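# Known false-positive rs-identifier surfaces (canonical lowercase form).
rs61443
rs61433
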