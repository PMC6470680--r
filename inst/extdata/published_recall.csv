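combo,segment,classifier,regular_mean,regular_sd,LC_mean,LC_sd,KB_mean,KB_sd
aw,PL,SVMl,0.81,0.31,0.82,0.16,0.78,0.07
aw,PL,SVMq,0.78,0.30,0.84,0.16,0.80,0.18
a,TH,SVMl,0.87,0.11,0.90,0.14,0.71,0.29
a,TH,SVMq,0.86,0.11,0.90,0.04,0.72,0.29
a,TH,SVMc,0.87,0.12,0.89,0.04,0.73,0.27
aw,TH,SVMl,0.79,0.24,0.91,0.07,0.74,0.30
aw,TH,SVMq,0.81,0.20,0.90,0.06,0.75,0.30
aw,TH,SVMc,0.83,0.17,0.83,0.16,0.74,0.29
a,SH,SVMl,0.80,0.14,0.85,0.12,0.88,0.05
a,SH,SVMq,0.91,0.05,0.89,0.06,0.90,0.04
a,SH,SVMc,0.90,0.05,0.88,0.06,0.88,0.05
a,SH,kNNf,0.79,0.23,0.81,0.08,0.81,0.14
a,SH,kNNw,0.77,0.25,0.82,0.06,0.83,0.11
aw,SH,SVMl,0.71,0.28,0.85,0.10,0.83,0.07
aw,SH,SVMq,0.86,0.10,0.90,0.05,0.86,0.06
aw,SH,SVMc,0.86,0.10,0.89,0.05,0.86,0.05
aw,SH,kNNw,0.81,0.18,0.81,0.09,0.81,0.09
a,FT,SVMl,0.86,0.15,0.85,0.05,0.88,0.06
a,FT,SVMq,0.87,0.14,0.87,0.07,0.86,0.09
a,FT,SVMc,0.89,0.08,0.87,0.08,0.85,0.08
a,FT,kNNf,0.90,0.13,0.75,0.14,0.81,0.12
a,FT,kNNco,0.85,0.19,0.83,0.10,0.80,0.14
a,FT,kNNw,0.89,0.14,0.76,0.14,0.82,0.10
a,FT,ANN,0.85,0.15,0.85,0.07,0.88,0.06
aw,FT,SVMl,0.81,0.20,0.84,0.07,0.89,0.06
aw,FT,SVMq,0.80,0.28,0.87,0.09,0.81,0.22
aw,FT,SVMc,0.81,0.26,0.84,0.08,0.84,0.16
aw,FT,kNNco,0.82,0.17,0.82,0.08,0.76,0.22
aw,FT,kNNw,0.85,0.17,0.76,0.10,0.82,0.17
aw,FT,ANN,0.82,0.17,0.83,0.09,0.76,0.29
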