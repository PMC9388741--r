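gene,score
DNMT1,-0.52
IGF1,-0.46
MAFB,-0.61
KDM6B,-0.44
WNT1,-0.55
WNT10B,-0.48
SOX9,-0.21
RUNX2,-0.35
PPARG,-0.62
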