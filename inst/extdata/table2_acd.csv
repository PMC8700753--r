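case,mcfi_areas,intraop_areas,intraop_detached
1,,,0
2,,,0
3,2;3,2;3,0
4,2;3,2;3,0
5,,,0
6,2,2,0
7,2;3,2;3,0
8,,,0
9,,,0
10,1,1,0
11,1,1,0
12,,,0
13,,,0
14,,,0
15,,1;2;3;4,1
16,,,0
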