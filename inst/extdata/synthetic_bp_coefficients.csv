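"sex","measure","intercept","a1","a2","a3","a4","h1","h2","h3","h4","sd"
"male","systolic",102.2,1.82,0.128,0.002,-0.0013,2.73,-0.196,-0.047,0.0095,10.7
"male","diastolic",61,0.68,0.1,0.019,-6e-04,1.66,-0.023,-0.031,0.0056,11.6
"female","systolic",102,1.7,0.116,-0.003,-0.0012,2.47,-0.068,-0.03,0.007,10.4
"female","diastolic",60.5,0.64,0.096,0.018,-5e-04,1.4,-0.001,-0.029,0.0044,10.9
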