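X_A	Y_A
X_C	Y_C
X_Ct	Y_Ct
Z_A1	Z_A2
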