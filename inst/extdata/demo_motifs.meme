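MEME version 4

ALPHABET= ACGT

Background letter frequencies
A 0.295 C 0.205 G 0.205 T 0.295

MOTIF DEMO1
letter-probability matrix: alength= 4 w= 7 nsites= 14
 0.857143 0.071429 0.071429 0.000000
 0.142857 0.000000 0.857143 0.000000
 0.000000 0.000000 0.071429 0.928571
 1.000000 0.000000 0.000000 0.000000
 0.000000 0.928571 0.071429 0.000000
 0.071429 0.071429 0.000000 0.857143
 0.214286 0.142857 0.571429 0.071429
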