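subset	reported_genes	protein_ids	mutagenesis_sites
common	455	499	98
meta_signature_only	829	813	162
ecd_signature_only	1852	1664	258
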