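dataset	attribute	pathogenic	benign	printed_rate
ClinVar	baseline	52634	118562	0.31
ProteinGym	baseline	32000	30727	0.51
ClinVar	disordered	5700	48845	0.10
ClinVar	ppi	6931	4445	0.61
ClinVar	hydrophobic	16173	40674	0.28
ProteinGym	ordered	28962	17985	0.62
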