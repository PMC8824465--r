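connection_class,distance_um,paired_found,paired_probed,opto_found,opto_probed
Exc. to exc.,0-100,8,135,12,205
Exc. to exc.,100-200,2,48,3,312
Exc. to Pvalb,0-100,13,28,19,41
Exc. to Pvalb,100-200,8,27,9,60
Exc. to VIP,0-100,6,25,7,24
Exc. to VIP,100-200,4,28,0,11
Sst to exc.,0-100,9,38,45,101
Sst to exc.,100-200,6,22,38,167
Sst to Pvalb,0-100,8,36,2,12
Sst to Pvalb,100-200,4,35,4,26
Pvalb to exc.,0-100,17,31,17,50
Pvalb to exc.,100-200,9,30,18,96
Pvalb to Pvalb,0-100,30,82,6,17
Pvalb to Pvalb,100-200,32,102,14,35
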