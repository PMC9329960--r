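patient	walking	turning
1	2	0
2	2	0
3	2	1
4	1	0
5	2	1
6	1	1
7	3	1
8	3	0
9	3	0
10	1	0
11	1	2
12	2	1
13	2	1
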