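sample	tissue	line	phenotype	replicate
p136.1	lung	lsc136	PKH26_plus	1
p136.2	lung	lsc136	PKH26_plus	2
p136.3	lung	lsc136	PKH26_plus	3
m136.1	lung	lsc136	PKH26_minus	1
m136.2	lung	lsc136	PKH26_minus	2
m136.3	lung	lsc136	PKH26_minus	3
p229.1	lung	lsc229	PKH26_plus	1
p229.2	lung	lsc229	PKH26_plus	2
p229.3	lung	lsc229	PKH26_plus	3
m229.1	lung	lsc229	PKH26_minus	1
m229.2	lung	lsc229	PKH26_minus	2
m229.3	lung	lsc229	PKH26_minus	3
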