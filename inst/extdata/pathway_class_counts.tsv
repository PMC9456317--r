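pathway	plus	minus	all
ANATOMICAL_STRUCTURE_FORMATION_INVOLVED_IN_MORPHOGENESIS	16	28	18
ANIMAL_ORGAN_MORPHOGENESIS	17	23	15
BLOOD_VESSEL_MORPHOGENESIS	7	17	7
EMBRYONIC_MORPHOGENESIS	7	12	8
HEART_MORPHOGENESIS	7	4	1
MORPHOGENESIS_OF_AN_EPITHELIUM	9	12	6
REGULATION_OF_ANATOMICAL_STRUCTURE_MORPHOGENESIS	12	24	14
TISSUE_MORPHOGENESIS	12	15	8
TUBE_DEVELOPMENT	14	23	11
TUBE_MORPHOGENESIS	11	22	9
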