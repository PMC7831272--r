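>planted
A [ 94  2  2  2  2 94  2  2  2 94 ]
C [  2 94  2  2 94  2  2  2 94  2 ]
G [  2  2 94  2  2  2  2 94  2  2 ]
T [  2  2  2 94  2  2 94  2  2  2 ]
>decoy_ttgacc
A [  2  2  2 94  2  2  2  2  2  2 ]
C [  2  2  2  2 94 94  2  2  2 94 ]
G [  2  2 94  2  2  2 94 94  2  2 ]
T [ 94 94  2  2  2  2  2  2 94  2 ]
>decoy_ggatcc
A [  2  2 94  2  2  2  2 94  2  2 ]
C [  2  2  2  2 94 94  2  2  2  2 ]
G [ 94 94  2  2  2  2  2  2  2 94 ]
T [  2  2  2 94  2  2 94  2 94  2 ]
>decoy_caacgg
A [  2 94 94  2  2  2  2  2 94  2 ]
C [ 94  2  2 94  2  2  2  2  2  2 ]
G [  2  2  2  2 94 94  2 94  2 94 ]
T [  2  2  2  2  2  2 94  2  2  2 ]
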