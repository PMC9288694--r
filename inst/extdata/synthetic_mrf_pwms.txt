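>synthetic_MYOD_ebox
A [  2 90  2  2  2  2 ]
C [ 90  2  4 90  2  2 ]
G [  4  4 90  4  2 90 ]
T [  4  4  4  4 94  6 ]
>synthetic_MYOG_ebox
A [  2 88 20 10  2  2 ]
C [ 88  4 10 20  2  2 ]
G [  6  4 60 10  2 90 ]
T [  4  4 10 60 94  6 ]
>synthetic_SP1_gcbox
A [  4  4  4  4  4  4 ]
C [  4  4  4 88  4  4 ]
G [ 88 88 88  4 88 88 ]
T [  4  4  4  4  4  4 ]
>synthetic_TBP_tata
A [  4 88  4 88 88 88 ]
C [  4  4  4  4  4  4 ]
G [  4  4  4  4  4  4 ]
T [ 88  4 88  4  4  4 ]
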