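component	eigenvalue	proportion	cumulative
1	9.874	0.987	0.987
2	0.042	0.004	0.991
3	0.025	0.003	0.994
4	0.015	0.002	0.996
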