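rsid	class	mirna	gene	database	validated
rs28457673	target_site	hsa-mir-15a	IGF1R	polymirts	FALSE
rs28457673	target_site	hsa-mir-15a	IGF1R	mirsnp	FALSE
rs28457673	target_site	hsa-mir-15b	IGF1R	polymirts	FALSE
rs28457673	target_site	hsa-mir-15b	IGF1R	mirnasnp	FALSE
rs28457673	target_site	hsa-mir-16	IGF1R	polymirts	TRUE
rs28457673	target_site	hsa-mir-16	IGF1R	mirsnp	TRUE
rs28457673	target_site	hsa-mir-195	IGF1R	mirnasnp	FALSE
rs28457673	target_site	hsa-mir-195	IGF1R	mirsnp	FALSE
rs28457673	target_site	hsa-mir-497	IGF1R	polymirts	TRUE
rs28457673	target_site	hsa-mir-497	IGF1R	mirnasnp	TRUE
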