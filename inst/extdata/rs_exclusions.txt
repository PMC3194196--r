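# Veto words: a capitalized RS/Rs match is rejected when any of these
# occurs in the document.
strain
strains
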