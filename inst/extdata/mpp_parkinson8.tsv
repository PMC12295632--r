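symbol	matched_symbols	category	note
SDHA	SDHA	mitochondrial_metabolism	
CS	CS	mitochondrial_metabolism	
PARK7	PARK7	oxidative_stress_response	
PSMA5	PSMA8	proteasomal_degradation	prose symbol PSMA5; the curated 40-protein table lists PSMA8
PSMB	PSMB3;PSMB5;PSMB10	proteasomal_degradation	prose symbol PSMB has no subunit number; table lists PSMB3, PSMB5 and PSMB10
PSMC3	PSMC1B	proteasomal_degradation	prose symbol PSMC3; closest curated table entry is PSMC1B
PSMC5	PSMC5	proteasomal_degradation	
PSMD11	PSMD11B	proteasomal_degradation	prose symbol PSMD11; curated table lists PSMD11B
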