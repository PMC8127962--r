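"t_s","intensity","is_prebleach"
0,1,TRUE
3,1,TRUE
6,1,TRUE
9,1,TRUE
12,1,TRUE
15,0.227419168942933,FALSE
18,0.23327948411606,FALSE
21,0.290200737608597,FALSE
24,0.328616243580253,FALSE
27,0.352465642912732,FALSE
30,0.366720212801046,FALSE
33,0.420128148831787,FALSE
36,0.406126739516168,FALSE
39,0.463986326465636,FALSE
42,0.435788834612266,FALSE
45,0.474695741836972,FALSE
48,0.504276937095381,FALSE
51,0.439327141746846,FALSE
54,0.468896521755968,FALSE
57,0.478147516231173,FALSE
60,0.498991256101605,FALSE
63,0.485285196519067,FALSE
66,0.441884758461536,FALSE
69,0.44968489735177,FALSE
72,0.527892084234656,FALSE
75,0.497935366240714,FALSE
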