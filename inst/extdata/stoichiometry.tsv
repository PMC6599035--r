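protein	subunits
Hcn4	4
Hcn1	4
Cacna1c	1
Cacna1h	1
Kcnh2	4
Kcnj3	4
Kcnj5	4
Kcnj8	4
Kcnj11	4
Kcnk3	2
Ryr2	4
Atp2a2	1
Slc8a1	1
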