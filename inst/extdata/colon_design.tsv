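sample	tissue	line	phenotype	replicate
PKH26+1	colon	crc1	PKH26_plus	1
PKH26+2	colon	crc1	PKH26_plus	2
PKH26+3	colon	crc1	PKH26_plus	3
PKH26+4	colon	crc1	PKH26_plus	4
PKH26+5	colon	crc1	PKH26_plus	5
PKH26-1	colon	crc1	PKH26_minus	1
PKH26-2	colon	crc1	PKH26_minus	2
PKH26-3	colon	crc1	PKH26_minus	3
PKH26-4	colon	crc1	PKH26_minus	4
PKH26-5	colon	crc1	PKH26_minus	5
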