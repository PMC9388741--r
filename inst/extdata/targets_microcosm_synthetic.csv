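gene
DNMT1
IGF1
MAFB
KDM6B
WNT1
WNT10B
SOX9
ACVR1
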