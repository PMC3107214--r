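>SYN_NFKB NF-kappaB-like
A [ 1 1 1 10 5 1 1 1 1 1 ]
C [ 1 1 1 5 10 1 1 1 17 17 ]
G [ 17 17 17 5 5 1 1 1 1 1 ]
T [ 1 1 1 5 5 17 17 17 1 1 ]
>SYN_RELA RELA-like
A [ 1 1 10 17 1 1 1 1 1 1 ]
C [ 1 1 5 1 1 1 1 17 17 17 ]
G [ 17 17 5 1 1 1 1 1 1 1 ]
T [ 1 1 5 1 17 17 17 1 1 1 ]
>SYN_SP1 SP1-like
A [ 1 1 1 1 5 1 1 1 1 1 ]
C [ 1 1 1 1 10 1 1 1 1 17 ]
G [ 17 17 17 17 5 17 17 17 17 1 ]
T [ 1 1 1 1 5 1 1 1 1 1 ]
>SYN_AP1 AP1-like
A [ 1 1 17 1 1 1 17 ]
C [ 1 1 1 17 1 17 1 ]
G [ 1 17 1 1 1 1 1 ]
T [ 17 1 1 1 17 1 1 ]
>SYN_IRF IRF-like
A [ 17 10 17 1 1 1 17 17 17 1 ]
C [ 1 5 1 1 1 1 1 1 1 1 ]
G [ 1 5 1 17 1 17 1 1 1 17 ]
T [ 1 5 1 1 17 1 1 1 1 1 ]
>SYN_SRF SRF-like
A [ 1 1 17 1 17 1 17 1 1 1 ]
C [ 17 17 1 1 1 1 1 1 1 1 ]
G [ 1 1 1 1 1 1 1 1 17 17 ]
T [ 1 1 1 17 1 17 1 17 1 1 ]
>SYN_TBP TATA-like
A [ 1 17 1 17 17 10 ]
C [ 1 1 1 1 1 5 ]
G [ 1 1 1 1 1 5 ]
T [ 17 1 17 1 1 5 ]
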