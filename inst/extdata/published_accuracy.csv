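combo,segment,classifier,mean,sd
a,PL,DTf,0.70,0.18
a,PL,SVMl,0.79,0.20
a,PL,SVMq,0.76,0.21
a,PL,SVMc,0.75,0.21
a,PL,kNNf,0.73,0.21
a,PL,kNNco,0.73,0.21
a,PL,kNNcu,0.73,0.18
a,PL,kNNw,0.73,0.23
a,PL,ANN,0.75,0.18
a,TH,DTf,0.75,0.05
a,TH,SVMl,0.83,0.11
a,TH,SVMq,0.83,0.10
a,TH,SVMc,0.83,0.10
a,TH,kNNf,0.77,0.09
a,TH,kNNco,0.77,0.11
a,TH,kNNcu,0.76,0.09
a,TH,kNNw,0.78,0.10
a,TH,ANN,0.79,0.10
a,SH,DTf,0.77,0.07
a,SH,SVMl,0.84,0.06
a,SH,SVMq,0.90,0.02
a,SH,SVMc,0.88,0.03
a,SH,kNNf,0.80,0.08
a,SH,kNNco,0.79,0.10
a,SH,kNNcu,0.79,0.07
a,SH,kNNw,0.81,0.03
a,SH,ANN,0.79,0.08
a,FT,DTf,0.74,0.06
a,FT,SVMl,0.86,0.05
a,FT,SVMq,0.87,0.05
a,FT,SVMc,0.87,0.03
a,FT,kNNf,0.83,0.04
a,FT,kNNco,0.82,0.05
a,FT,kNNcu,0.79,0.04
a,FT,kNNw,0.82,0.03
a,FT,ANN,0.86,0.04
w,PL,DTf,0.66,0.16
w,PL,SVMl,0.72,0.19
w,PL,SVMq,0.76,0.21
w,PL,SVMc,0.75,0.21
w,PL,kNNf,0.73,0.22
w,PL,kNNco,0.73,0.21
w,PL,kNNcu,0.72,0.20
w,PL,kNNw,0.74,0.22
w,PL,ANN,0.69,0.21
w,TH,DTf,0.70,0.10
w,TH,SVMl,0.79,0.09
w,TH,SVMq,0.79,0.09
w,TH,SVMc,0.79,0.08
w,TH,kNNf,0.75,0.09
w,TH,kNNco,0.76,0.09
w,TH,kNNcu,0.73,0.08
w,TH,kNNw,0.76,0.10
w,TH,ANN,0.72,0.13
w,SH,DTf,0.69,0.06
w,SH,SVMl,0.73,0.12
w,SH,SVMq,0.74,0.12
w,SH,SVMc,0.74,0.12
w,SH,kNNf,0.73,0.08
w,SH,kNNco,0.73,0.10
w,SH,kNNcu,0.70,0.09
w,SH,kNNw,0.74,0.08
w,SH,ANN,0.71,0.08
w,FT,DTf,0.71,0.06
w,FT,SVMl,0.76,0.15
w,FT,SVMq,0.75,0.15
w,FT,SVMc,0.74,0.18
w,FT,kNNf,0.73,0.17
w,FT,kNNco,0.74,0.18
w,FT,kNNcu,0.70,0.16
w,FT,kNNw,0.74,0.17
w,FT,ANN,0.73,0.15
aw,PL,DTf,0.72,0.16
aw,PL,SVMl,0.80,0.18
aw,PL,SVMq,0.81,0.18
aw,PL,SVMc,0.79,0.20
aw,PL,kNNf,0.78,0.19
aw,PL,kNNco,0.77,0.20
aw,PL,kNNcu,0.75,0.19
aw,PL,kNNw,0.78,0.19
aw,PL,ANN,0.74,0.22
aw,TH,DTf,0.76,0.08
aw,TH,SVMl,0.81,0.10
aw,TH,SVMq,0.82,0.11
aw,TH,SVMc,0.80,0.10
aw,TH,kNNf,0.79,0.08
aw,TH,kNNco,0.79,0.10
aw,TH,kNNcu,0.74,0.09
aw,TH,kNNw,0.79,0.08
aw,TH,ANN,0.76,0.11
aw,SH,DTf,0.78,0.08
aw,SH,SVMl,0.80,0.10
aw,SH,SVMq,0.88,0.04
aw,SH,SVMc,0.87,0.04
aw,SH,kNNf,0.79,0.07
aw,SH,kNNco,0.79,0.08
aw,SH,kNNcu,0.78,0.07
aw,SH,kNNw,0.81,0.07
aw,SH,ANN,0.78,0.10
aw,FT,DTf,0.71,0.09
aw,FT,SVMl,0.85,0.08
aw,FT,SVMq,0.83,0.15
aw,FT,SVMc,0.83,0.14
aw,FT,kNNf,0.79,0.14
aw,FT,kNNco,0.80,0.13
aw,FT,kNNcu,0.75,0.18
aw,FT,kNNw,0.81,0.11
aw,FT,ANN,0.80,0.14
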