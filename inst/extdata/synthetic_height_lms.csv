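"sex","age_months","L","M","S"
"male",96,1,128.05,0.043
"male",102,1,130.58,0.0434
"male",108,1,133.13,0.0438
"male",114,1,135.72,0.0442
"male",120,1,138.35,0.0446
"male",126,1,141.07,0.045
"male",132,1,143.91,0.0454
"male",138,1,146.93,0.0458
"male",144,1,150.19,0.0462
"male",150,1,153.73,0.0466
"male",156,1,157.53,0.047
"male",162,1,161.5,0.0474
"male",168,1,165.47,0.0478
"male",174,1,169.27,0.0482
"male",180,1,172.81,0.0486
"male",186,1,176.07,0.049
"male",192,1,179.09,0.0494
"male",198,1,181.93,0.0498
"male",204,1,184.65,0.0502
"male",210,1,187.28,0.0506
"male",216,1,189.87,0.051
"male",222,1,192.42,0.0514
"female",96,1,127.43,0.042
"female",102,1,130.53,0.0423
"female",108,1,133.81,0.0426
"female",114,1,137.34,0.0429
"female",120,1,141.19,0.0432
"female",126,1,145.28,0.0435
"female",132,1,149.43,0.0438
"female",138,1,153.27,0.0441
"female",144,1,156.47,0.0444
"female",150,1,158.87,0.0447
"female",156,1,160.63,0.045
"female",162,1,162.08,0.0453
"female",168,1,163.59,0.0456
"female",174,1,165.34,0.0459
"female",180,1,167.41,0.0462
"female",186,1,169.73,0.0465
"female",192,1,172.23,0.0468
"female",198,1,174.85,0.0471
"female",204,1,177.54,0.0474
"female",210,1,180.28,0.0477
"female",216,1,183.05,0.048
"female",222,1,185.83,0.0483
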