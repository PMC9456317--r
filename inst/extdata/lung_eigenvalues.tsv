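component	eigenvalue	proportion	cumulative
1	5.970	0.498	0.498
2	1.154	0.096	0.594
3	0.906	0.076	0.670
4	0.599	0.050	0.720
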