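combo,segment,classifier,overall_mean,overall_sd,regular_mean,regular_sd,LC_mean,LC_sd,KB_mean,KB_sd
a,SH,SVMl,0.85,0.08,0.79,0.17,0.93,0.05,0.82,0.10
a,SH,SVMq,0.90,0.01,0.89,0.05,0.92,0.05,0.89,0.04
a,SH,SVMc,0.90,0.02,0.89,0.04,0.92,0.05,0.89,0.04
aw,SH,SVMq,0.89,0.02,0.88,0.04,0.91,0.06,0.90,0.05
aw,SH,SVMc,0.89,0.02,0.87,0.04,0.91,0.06,0.89,0.05
aw,SH,kNNw,0.85,0.08,0.79,0.05,0.94,0.05,0.82,0.14
a,FT,SVMl,0.88,0.06,0.84,0.06,0.95,0.04,0.85,0.10
a,FT,SVMq,0.89,0.05,0.86,0.07,0.94,0.07,0.87,0.08
a,FT,SVMc,0.89,0.03,0.86,0.07,0.93,0.07,0.88,0.07
a,FT,kNNco,0.85,0.05,0.79,0.05,0.89,0.06,0.85,0.07
a,FT,ANN,0.83,0.05,0.82,0.06,0.79,0.09,0.88,0.05
aw,FT,SVMl,0.86,0.07,0.79,0.06,0.93,0.07,0.84,0.12
aw,FT,SVMq,0.83,0.04,0.78,0.14,0.88,0.19,0.82,0.17
aw,FT,SVMc,0.84,0.05,0.79,0.10,0.89,0.18,0.84,0.12
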