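# name=gt_footprint_synthetic
A 1 4 41 2 1 3 41 40 1 3
C 4 1 5 3 3 5 7 5 42 40
G 1 1 3 6 40 4 1 3 4 5
T 44 44 1 39 6 38 1 2 3 2
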