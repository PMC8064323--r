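>SYN0001 GCbox ZF
A [  1  1  1  1  1 17  1  1  1  1 ]
C [  1  1  1  1 17  1  1  1  1 17 ]
G [ 17 17 17 17  1  1 17 17 17  1 ]
T [  1  1  1  1  1  1  1  1  1  1 ]
>SYN0002 CRElike BZIP
A [  1 17  1  1  1  1  1 17 ]
C [  1  1  1 17  1  1 17  1 ]
G [  1  1 17  1  1 17  1  1 ]
T [ 17  1  1  1 17  1  1  1 ]
>SYN0003 Ebox BHLH
A [  1 17 17  1  1  1  1  1 ]
C [  1  1  1 17  1  1  1 17 ]
G [ 17  1  1  1 17  1 17  1 ]
T [  1  1  1  1  1 17  1  1 ]
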