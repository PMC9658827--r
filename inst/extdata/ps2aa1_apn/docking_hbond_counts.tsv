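top	model_id	hbond_count
1	560	9
2	3413	9
3	105	9
4	819	8
5	994	8
6	2079	8
7	3521	8
8	1015	8
9	1742	8
10	708	8
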