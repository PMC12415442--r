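code,name
0,background
1,lepidic
2,acinar
3,papillary
4,micropapillary
5,solid
6,complex_glandular
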