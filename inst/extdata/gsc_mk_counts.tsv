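gene	syn_poly	syn_div	nonsyn_poly	nonsyn_div	printed_p
cycA	17	14	4	6	0.414
mei-P26	24	44	0	0	NA
nos	11	11	7	23	0.046
piwi	84	54	26	22	0.416
pum	77	51	11	5	0.506
stwl	45	62	48	124	0.015
Yb	86	62	80	149	0.00001
zpg	53	14	6	4	0.230
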