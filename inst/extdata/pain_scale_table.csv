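"pain_frequency","pain_intensity","pain_scale"
0,0,0
0,1,0
0,2,0
0,3,0
1,0,1
1,1,1
1,2,1
1,3,2
2,0,2
2,1,2
2,2,2
2,3,3
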