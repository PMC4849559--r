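"sex","age_lo","age_hi","base_utility"
"female",18,24,0.94
"female",25,34,0.93
"female",35,44,0.9
"female",45,54,0.85
"female",55,64,0.81
"female",65,74,0.76
"female",75,84,0.71
"female",85,120,0.65
"male",18,24,0.94
"male",25,34,0.93
"male",35,44,0.91
"male",45,54,0.85
"male",55,64,0.8
"male",65,74,0.78
"male",75,84,0.75
"male",85,120,0.68
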