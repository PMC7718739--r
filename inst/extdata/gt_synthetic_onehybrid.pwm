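# name=gt_onehybrid_synthetic
A 1 1 20 2 2 1 22 23 2 4
C 3 3 4 1 1 2 0 1 22 20
G 1 2 0 3 21 1 0 1 0 2
T 21 20 2 20 2 22 4 1 2 0
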