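IGF1R	3'-UTR miRSNP rs28457673 binding-site gene
BDNF	nerve growth factor family risk gene
NTRK2	neurotrophic receptor tyrosine kinase 2
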