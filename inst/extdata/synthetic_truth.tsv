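protein_id	start	end	config
synthetic_protein_001	460	470	2-3-2
synthetic_protein_002	226	234	1-3-1
synthetic_protein_003	150	160	3-2-2
synthetic_protein_004	175	184	3-1-2
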