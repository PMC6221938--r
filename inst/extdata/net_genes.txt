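# Seed list of neuroendocrine-tumor-associated genes; replace or extend with
# a curated list for real analyses.
MEN1
DAXX
ATRX
EPAS1
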