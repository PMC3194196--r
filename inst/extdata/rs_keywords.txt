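# Trigger words required in the document before a capitalized RS/Rs match
# is accepted.
mutation
mutations
SNP
SNPs
polymorphism
polymorphisms
variant
variants
allele
alleles
genotype
genotyped
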