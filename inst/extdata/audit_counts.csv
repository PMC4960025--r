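"pathway_id","count","source"
1,9,"narrative"
2,9,"inferred"
3,1,"inferred"
4,7,"narrative"
5,0,"narrative"
6,23,"narrative"
7,3,"narrative"
8,4,"narrative"
9,12,"narrative"
10,16,"narrative"
11,7,"narrative"
12,8,"narrative"
13,15,"narrative"
14,9,"narrative"
15,18,"narrative"
16,8,"narrative"
17,0,"narrative"
18,0,"narrative"
19,11,"narrative"
20,0,"narrative"
21,1,"narrative"
22,32,"narrative"
23,5,"narrative"
24,3,"narrative"
25,3,"narrative"
26,3,"narrative"
27,9,"narrative"
28,0,"narrative"
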