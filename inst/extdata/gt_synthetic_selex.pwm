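# name=gt_selex_synthetic
A 4 4 65 3 3 1 62 65 10 7
C 2 4 6 3 7 5 9 7 61 65
G 8 4 4 9 64 7 3 6 4 4
T 66 68 5 65 6 67 6 2 5 4
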