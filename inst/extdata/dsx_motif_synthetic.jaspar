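>MASYN001 DSX_SYNTHETIC
A [   1   1 997 997   1 997 997   1   1   1 997 997   1 ]
C [   1 997   1   1 997   1   1   1   1   1   1   1 997 ]
G [ 997   1   1   1   1   1   1   1 997   1   1   1   1 ]
T [   1   1   1   1   1   1   1 997   1 997   1   1   1 ]
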