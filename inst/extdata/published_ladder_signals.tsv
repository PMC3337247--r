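peptide_id	mz	z
prod1	1512.89	3
prod1	1135.07	4
prod2	1532.58	3
prod2	1149.31	4
prod3	1569.89	3
prod3	1177.72	4
prod4	1608.30	3
prod4	1206.14	4
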