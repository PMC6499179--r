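clade	n	genera
Papilionoid-derived	6	4
Papilionoid-derived	7	21
Papilionoid-derived	8	57
Papilionoid-derived	9	36
Papilionoid-derived	10	39
Papilionoid-derived	11	77
Papilionoid-derived	12	6
Papilionoid-derived	14	5
Papilionoid-derived	16	6
Papilionoid-derived	17	27
Papilionoid-grade	11	3
Papilionoid-early	8	2
Papilionoid-early	11	1
Papilionoid-early	13	4
Papilionoid-early	14	4
Papilionoid-early	16	1
Papilionoid-early	17	1
Caesalp-mimosoid	8	1
Caesalp-mimosoid	12	1
Caesalp-mimosoid	13	31
Caesalp-mimosoid	14	5
Caesalp-mimosoid	17	3
Caesalp-early	8	1
Caesalp-early	10	1
Caesalp-early	11	1
Caesalp-early	12	13
Caesalp-early	13	4
Caesalp-early	14	12
Dialidoideae	12	1
Dialidoideae	14	5
Detarioideae	6	1
Detarioideae	11	1
Detarioideae	12	19
Detarioideae	17	2
Cercidoideae	7	1
Cercidoideae	14	4
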