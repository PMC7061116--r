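6e4f95abb9c5a7c981bb66e800150b907dbaff885d3dec005785c6e4fd7a68af curated_variants.tsv
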