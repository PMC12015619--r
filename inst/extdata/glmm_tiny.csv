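hospital_id,broad_spectrum_use
A,1
A,1
A,1
A,1
A,0
A,1
B,0
B,0
B,1
B,0
B,0
B,0
B,0
B,1
C,1
C,0
C,1
C,1
C,0
C,1
C,0
C,0
C,1
C,1
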