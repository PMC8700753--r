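case,mcfi_areas,mcfi_subtype,intraop_areas,intraop_subtype,intraop_detached
1,,,,,0
2,2;3,protrusion,2;3,protrusion,0
3,,,,,0
4,,,,,0
5,2;3,protrusion,2;3,protrusion,0
6,,,,,0
7,,,,,0
8,2;3,protrusion,2;3,protrusion,0
9,2;3,protrusion,2;3,protrusion,0
10,1;2;3;4,flattening,1;2;3;4,flattening,0
11,1;2;3;4,flattening,1;2;3;4,flattening,0
12,2;3,protrusion,2;3,protrusion,0
13,2;3,protrusion,2;3,protrusion,0
14,2;3,protrusion,2;3,protrusion,0
15,1;2;3;4,protrusion,1;2;3;4,,1
16,2;3,protrusion,2;3,protrusion,0
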