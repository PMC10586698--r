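mean,hpd_lower,hpd_upper,status
0.11,0.089,0.31,N
0.44,0.29,0.67,Y
-0.069,-0.24,0.11,N
-0.96,-1.54,-0.37,N
-0.17,NA,NA,N
1,NA,NA,Y
1.37,1.34,1.40,Y
0.48,0.43,0.52,Y
1.51,1.46,1.55,Y
0.44,0.38,0.48,Y
0.54,0.49,0.57,Y
0.50,0.46,0.54,Y
1.55,1.51,1.60,Y
-1.18,-1.19,-1.17,N
-1.26,-1.26,-1.24,N
-1.74,-1.75,-1.73,N
-2.32,-2.33,-2.306,N
-1.55,-1.55,-1.539,N
-1.20,-1.20,-1.186,N
-1.45,-1.46,-1.44,N
-2.13,-2.14,-2.127,N
-1.58,-1.587,-1.572,N
-1.30,-1.31,-1.299,N
-1.18,-1.19,-1.177,N
-1.43,NA,NA,N
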