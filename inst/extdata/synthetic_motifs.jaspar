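>SYN_CRE synthetic CREB/ATF-like palindrome (TGACGTCA)
A  [  2  1 28  1  1  1  1 28 ]
C  [  1  1  1 28  1  1 28  1 ]
G  [  1 28  1  1 28  1  1  1 ]
T  [ 28  2  2  2  0 29  2  2 ]
>SYN_TATA synthetic TATA-box-like motif (TATAAATA)
A  [  1 27  1 26 26 25  2 26 ]
C  [  1  1  1  1  1  1  1  1 ]
G  [  1  1  1  1  1  2  1  1 ]
T  [ 29  3 29  4  4  4 28  4 ]
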