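id	window	nes_start	c1	c2	c3
synthetic_nes_01	NALRLSVELQELWLPTCVRSGGEQT	3	1	3	2
synthetic_nes_02	INPIVKQALDERVAWLTVESDQPAD	5	3	3	2
synthetic_nes_03	IVEVLYGLADIKSAEMEPVMLNGRE	8	2	2	1
synthetic_nes_04	RFRDPITQITLPYNINRKGDSIGHL	2	3	2	1
synthetic_nes_05	QPQKRKKLDMRLQRLEILTICMSSH	8	1	1	2
synthetic_nes_06	VYEERFITTFFDDLKPLGEVNIKSV	11	2	2	2
synthetic_nes_07	FIKDFDFALIITERNSHLRIKVLRQ	2	2	1	1
synthetic_nes_08	GRRLRDLNTVALGEDLDGRSTTGVR	4	2	2	1
synthetic_nes_09	SIDGQLISNLPSLDELAKHNPQVVY	7	2	2	2
synthetic_nes_10	GFTAEIIDEFSLEIESACHWKFIEE	7	2	1	1
synthetic_nes_11	LRFFELEGSLELEDVGSAITCPNYT	6	3	1	2
synthetic_nes_12	TFNKFEPDLLGMELGTVKLAVVAEL	5	3	2	1
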