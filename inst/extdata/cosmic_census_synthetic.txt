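# SYNTHETIC stand-in for a cancer gene census list (the real census is
# licensed and cannot be redistributed). For real analyses supply your own
# census file via --cosmic-genes / annotate_gene_sets().
TP53
KRAS
ERG
BUB1
MYH11
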