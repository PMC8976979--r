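>SYNTH001.1 SYNTH_TATA (synthetic TATA-box-like PFM, not a JASPAR record)
A  [  4 92  4 88 70 82 ]
C  [  2  2  2  2  4  4 ]
G  [  2  2  2  4 20  8 ]
T  [ 92  4 92  6  6  6 ]
>SYNTH002.1 SYNTH_INR (synthetic initiator-like PFM, not a JASPAR record)
A  [  8  4 78  6 22 10 44 ]
C  [ 50 84  6 48 22 50 18 ]
G  [ 12  4  8  8  14 10 22 ]
T  [ 30  8  8 38 42 30 16 ]
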