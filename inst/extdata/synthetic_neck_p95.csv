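"sex","age_years","p95_cm"
"male",8,30
"male",9,30.9
"male",10,31.7
"male",11,32.5
"male",12,33.4
"male",13,34.2
"male",14,35.1
"male",15,36
"male",16,36.8
"male",17,37.6
"male",18,38.5
"female",8,29
"female",9,29.6
"female",10,30.3
"female",11,31
"female",12,31.6
"female",13,32.2
"female",14,32.9
"female",15,33.5
"female",16,34.2
"female",17,34.9
"female",18,35.5
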