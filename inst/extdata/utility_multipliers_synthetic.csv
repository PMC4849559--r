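"name","value"
"condition_cad",0.93
"post_mi",0.88
"post_is",0.82
"post_hs",0.76
"acute_mi",0.85
"acute_is",0.8
"acute_hs",0.75
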