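comparison,found_1,probed_1,found_2,probed_2
Rorb L4 vs Rorb L5,148,1511,71,1028
L5 Rorb vs L5 Tlx3,71,1028,61,1052
Sst Ai167 L4 vs Sst AAV L4,2,19,51,248
Pvalb intralaminar vs Sst intralaminar,35,156,60,211
L5 Pvalb vs L5 Sst,2,259,16,252
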