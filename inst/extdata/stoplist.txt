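# Surfaces that look like variant mentions but denote other concepts
# (cell lines, transcription factors, chemicals, ...). One entry per line.
C3H
E2F
H2S
T47D
L5178Y
T1D
T98G
H295R
P4501A
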