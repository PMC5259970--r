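# TaqI (TCGA) partial digest of the luciferase gene (2009 bp):
# all pairwise distances among the six internal cut sites and the two ends.
9 30 100 170 293 302 393 402 462 562 632 732 855 864
945 954 975 984 1025 1034 1247 1277 1347 1377 1809 1839 1979 2009
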