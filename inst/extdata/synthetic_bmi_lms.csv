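"sex","age_months","L","M","S"
"male",96,-2.4,16.3,0.145
"male",102,-2.38,16.578,0.144
"male",108,-2.36,16.862,0.143
"male",114,-2.34,17.152,0.142
"male",120,-2.32,17.448,0.141
"male",126,-2.3,17.75,0.14
"male",132,-2.28,18.058,0.139
"male",138,-2.26,18.372,0.138
"male",144,-2.24,18.692,0.137
"male",150,-2.22,19.018,0.136
"male",156,-2.2,19.35,0.135
"male",162,-2.18,19.688,0.134
"male",168,-2.16,20.032,0.133
"male",174,-2.14,20.382,0.132
"male",180,-2.12,20.738,0.131
"male",186,-2.1,21.1,0.13
"male",192,-2.08,21.468,0.129
"male",198,-2.06,21.842,0.128
"male",204,-2.04,22.222,0.127
"male",210,-2.02,22.608,0.126
"male",216,-2,23,0.125
"male",222,-1.98,23.398,0.124
"female",96,-2.15,16.1,0.15
"female",102,-2.135,16.403,0.149
"female",108,-2.12,16.71,0.148
"female",114,-2.105,17.023,0.147
"female",120,-2.09,17.34,0.146
"female",126,-2.075,17.663,0.145
"female",132,-2.06,17.99,0.144
"female",138,-2.045,18.323,0.143
"female",144,-2.03,18.66,0.142
"female",150,-2.015,19.003,0.141
"female",156,-2,19.35,0.14
"female",162,-1.985,19.702,0.139
"female",168,-1.97,20.06,0.138
"female",174,-1.955,20.422,0.137
"female",180,-1.94,20.79,0.136
"female",186,-1.925,21.163,0.135
"female",192,-1.91,21.54,0.134
"female",198,-1.895,21.923,0.133
"female",204,-1.88,22.31,0.132
"female",210,-1.865,22.702,0.131
"female",216,-1.85,23.1,0.13
"female",222,-1.835,23.503,0.129
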