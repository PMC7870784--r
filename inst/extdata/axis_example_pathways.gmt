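hsa04010	MAPK signaling pathway | Environmental information processing (signal transduction)	IGF1R	BDNF	NTRK2	SYNG01	SYNG02	SYNG03	SYNG04	SYNG05	SYNG06	SYNG07
hsa04151	PI3K-Akt signaling pathway | Environmental information processing (signal transduction)	IGF1R	BDNF	NTRK2	SYNG08	SYNG09	SYNG10	SYNG11	SYNG12	SYNG13	SYNG14
hsa01521	EGFR tyrosine kinase inhibitor resistance | Human Diseases (Drug resistance: antineoplastic)	IGF1R	BDNF	SYNG15	SYNG16	SYNG17	SYNG18	SYNG19	SYNG20	SYNG21	SYNG22
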