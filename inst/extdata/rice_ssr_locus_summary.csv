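marker,min_allele,max_allele,n_alleles,gene_diversity
RM1,67,119,4,0.534
RM452,192,213,4,0.654
RM338,178,184,4,0.456
RM124,257,289,3,0.789
RM162,191,244,2,0.549
RM118,149,165,3,0.687
RM433,216,248,3,0.827
RM316,194,216,4,0.597
RM271,80,120,4,0.751
RM144,216,295,4,0.652
RM19,192,250,4,0.745
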