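mirna	gene	source
hsa-mir-15a	IGF1R	targetscan
hsa-mir-15a	IGF1R	miranda
hsa-mir-15a	IGF1R	pita
hsa-mir-15a	IGF1R	rna22
hsa-mir-15b	IGF1R	targetscan
hsa-mir-15b	IGF1R	miranda
hsa-mir-15b	IGF1R	pita
hsa-mir-15b	IGF1R	rnahybrid
hsa-mir-15b	IGF1R	rna22
hsa-mir-16	IGF1R	targetscan
hsa-mir-16	IGF1R	miranda
hsa-mir-16	IGF1R	pita
hsa-mir-16	IGF1R	rna22
hsa-mir-195	IGF1R	targetscan
hsa-mir-195	IGF1R	miranda
hsa-mir-195	IGF1R	rnahybrid
hsa-mir-195	IGF1R	rna22
hsa-mir-497	IGF1R	targetscan
hsa-mir-497	IGF1R	miranda
hsa-mir-497	IGF1R	pita
hsa-mir-497	IGF1R	rnahybrid
hsa-mir-497	IGF1R	rna22
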