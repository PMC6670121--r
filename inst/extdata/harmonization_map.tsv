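fine_term	broad_category
exonic_coding	exonic
splice_site	splicing
splice_region	splicing
ncRNA_exonic	ncRNA_exonic
UTR5	UTR5
UTR3	UTR3
intronic	intronic
upstream	upstream
downstream	downstream
intergenic	intergenic
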