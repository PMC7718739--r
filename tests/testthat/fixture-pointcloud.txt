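# embryo_id=fix01
# genotype=minWT
# stain_id=stainA
# stage_pct=6
# anterior=lowx
# ventral=lowy
# columns=nucleus_id,x,y,z,lacZ,hkb,ftz
1,0,-10,0,1.5,0.2,3
2,60,-8,4,2.25,0.4,2.5
3,125,0,-10,7.5,0.1,0
4,190,9,3,3,0.8,1.25
5,250,2,10,0.5,6,0.75
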